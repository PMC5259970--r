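#' Number of pairwise distances among n points
#'
#' `pair_count(n)` is `n * (n - 1) / 2`, the size of the difference multiset
#' of an `n`-point map; `n_from_pair_count(N)` inverts it exactly, returning
#' `NA` when `N` is not a triangular number. The inverse starts from the
#' closed form `(1 + sqrt(1 + 8 N)) / 2` and then verifies integrally in a
#' small window, so it is immune to floating-point rounding for large `N`.
#'
#' @param n Number of points (restriction sites plus the two molecule ends).
#' @param N A candidate pair count.
#' @return `pair_count`: an integer (numeric for very large `n`).
#'   `n_from_pair_count`: the unique integer `n >= 2` with
#'   `n * (n - 1) / 2 == N`, or `NA`.
#' @examples
#' pair_count(40)            # 780
#' n_from_pair_count(103285) # 455
#' @export
pair_count <- function(n) {
  n <- as_scalar_int(n, "n")
  as.numeric(n) * (n - 1) / 2
}

#' @rdname pair_count
#' @export
n_from_pair_count <- function(N) {
  if (length(N) != 1L || is.na(N) || N != trunc(N) || N < 1)
    return(NA_integer_)
  guess <- floor((1 + sqrt(1 + 8 * as.numeric(N))) / 2)
  for (cand in (guess - 2):(guess + 2)) {
    if (cand >= 2 && cand * (cand - 1) / 2 == N) return(as.integer(cand))
  }
  NA_integer_
}

#' Validate a partial digest instance
#'
#' Checks that `D` is a non-empty multiset of positive integers whose size is
#' a triangular number `n(n-1)/2`, and packages it with the recovered point
#' count `n` and the map width (the largest distance).
#'
#' @param D A distance multiset ([dms()]) or integer vector.
#' @return A `pdp_instance`: list with elements `D`, `N`, `n`, `width`.
#' @examples
#' pdp_instance(c(1, 2, 2, 3, 5, 6, 7, 8, 8, 10))
#' @export
pdp_instance <- function(D) {
  D <- dms(D)
  N <- dms_size(D)
  if (N == 0L)
    pdp_error("instance multiset is empty", "pdp_empty_input_error")
  if (D$value[1L] <= 0L)
    pdp_error("instance distances must be positive integers",
              "pdp_nonpositive_error")
  n <- n_from_pair_count(N)
  if (is.na(n))
    pdp_error(sprintf(
      "multiset size %d is not of the form n(n-1)/2 for any integer n >= 2", N),
      "pdp_nontriangular_error")
  structure(list(D = D, N = N, n = n, width = dms_max(D)),
            class = "pdp_instance")
}

as_pdp_instance <- function(x) {
  if (inherits(x, "pdp_instance")) x else pdp_instance(x)
}

#' @export
print.pdp_instance <- function(x, ...) {
  cat(sprintf("<partial digest instance: N = %d distances, n = %d points, width = %d>\n",
              x$N, x$n, x$width))
  invisible(x)
}
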