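# Independent brute-force machinery used to cross-check the solvers and the
# multiset algebra. Deliberately built on plain sorted vectors and stats::dist
# so it shares no code path with the package internals.

# all pairwise absolute differences of a 1-d point set, sorted
oracle_delta <- function(X) sort(as.integer(stats::dist(X)))

# remove elements of l from d one occurrence at a time (count model)
oracle_vec_diff <- function(d, l) {
  for (x in l) {
    i <- match(x, d)
    if (!is.na(i)) d <- d[-i]
  }
  sort(d)
}

# enumerate every point set X (anchored at 0, containing the width) whose
# difference multiset equals d_vec; feasible for n <= 7 or so
oracle_solve <- function(d_vec) {
  d_vec <- sort(as.integer(d_vec))
  N <- length(d_vec)
  n <- which(vapply(2:60, function(k) k * (k - 1) / 2, numeric(1)) == N) + 1L
  stopifnot(length(n) == 1L)
  width <- max(d_vec)
  inner <- setdiff(unique(d_vec), width)
  sols <- list()
  if (n == 2L) {
    if (identical(oracle_delta(c(0L, width)), d_vec))
      sols <- list(c(0L, width))
  } else if (length(inner) >= n - 2L) {
    picks <- utils::combn(inner, n - 2L, simplify = FALSE)
    for (p in picks) {
      X <- sort(c(0L, p, width))
      if (identical(oracle_delta(X), d_vec))
        sols[[length(sols) + 1L]] <- X
    }
  }
  sols
}

# canonical string form of a list of point sets, for set comparison
canon_sols <- function(sols) {
  sort(vapply(sols, paste, character(1), collapse = " "))
}

expect_same_solutions <- function(got, expected_list) {
  expect_identical(canon_sols(got$solutions), canon_sols(expected_list))
}

worked_example <- c(1L, 2L, 2L, 3L, 5L, 6L, 7L, 8L, 8L, 10L)
worked_solutions <- list(c(0L, 2L, 3L, 8L, 10L), c(0L, 2L, 7L, 8L, 10L))

luciferase_sites <- c(30L, 975L, 984L, 1277L, 1377L, 1839L)
luciferase_solutions <- list(
  c(0L, 30L, 975L, 984L, 1277L, 1377L, 1839L, 2009L),
  c(0L, 170L, 632L, 732L, 1025L, 1034L, 1979L, 2009L)
)
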