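#' Generate a random partial digest instance
#'
#' Draws a map of `n` distinct sites — the origin plus `n - 1` coordinates
#' sampled uniformly without replacement from `1..max_coord` — and returns it
#' with its difference multiset. This is the average-case benchmark family:
#' typical studies take `max_coord = n * q` with `q` in 10, 100, 1000, 10000
#' (small `q` crowds the sites together and raises the rate of repeated
#' distances, the regime where duplicate-subproblem elimination pays off).
#'
#' The map is anchored at 0 so that, solutions being reported anchored at 0,
#' the generating map itself (and its mirror) always appears verbatim in the
#' solver output.
#'
#' @param n Number of points (`>= 2`).
#' @param max_coord Largest allowed coordinate; must be at least `n - 1`.
#' @param seed Optional integer seed; when given, generation is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A list with `points` (the generating map) and `D` (its [dms()]).
#' @examples
#' random_instance(5, 50, seed = 1)
#' @export
random_instance <- function(n, max_coord, seed = NULL) {
  n <- as_scalar_int(n, "n")
  max_coord <- as_scalar_int(max_coord, "max_coord")
  if (n < 2L)
    pdp_error("n must be at least 2", "pdp_infeasible_params_error")
  if (max_coord < n - 1L)
    pdp_error(sprintf("max_coord = %d leaves no room for %d distinct positive coordinates",
                      max_coord, n - 1L),
              "pdp_infeasible_params_error")
  draw <- function() c(0L, sort.int(sample.int(max_coord, n - 1L)))
  X <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(points = X, D = delta_set(X))
}

#' Generate an adversarial (Zhang-type) instance
#'
#' Builds the classical worst-case family for depth-first partial digest
#' search. On the unit interval scaled to integer width `W = scale`, five
#' arithmetic blocks of `n_blocks` points each are laid down with step `eps`:
#' near-left blocks `A2 = {eps..n eps}` and `A4 = {(2n+1)eps..3n eps}`,
#' near-right mirror blocks `A1 = {W - n eps..W - eps}` and
#' `A5 = {W - 3n eps..W - (2n+1) eps}`, and a middle block derived from
#' `A3 = {(n+1)eps..2n eps}` in which each element is kept either on the left
#' (`a`) or reflected to the right (`W - a`) by a seeded fair coin. Together
#' with the interval ends the map has `5 n_blocks + 2` points. The heavy
#' left/right symmetry makes both `y` and `width - y` placements feasible
#' deep into the search, forcing exponentially many subproblems on a
#' depth-first solver — almost all of them duplicates, which the
#' breadth-first solvers remove.
#'
#' The step bound `12 * n_blocks * eps < scale` keeps all blocks disjoint
#' inside the interval; the generator additionally verifies distinctness.
#'
#' @param n_blocks Points per block (`n` of the construction); the map has
#'   `5 * n_blocks + 2` points.
#' @param scale Integer interval width `W`; default `1000 * n_blocks`.
#' @param eps Integer block step; default is the largest integer below
#'   `scale / (12 * n_blocks + 1)`.
#' @param seed Optional seed for the left/right coin of the middle block.
#' @return A list with `points` and `D`, as [random_instance()].
#' @examples
#' zhang_instance(3, seed = 1)
#' @export
zhang_instance <- function(n_blocks, scale = 1000L * n_blocks, eps = NULL,
                           seed = NULL) {
  n <- as_scalar_int(n_blocks, "n_blocks")
  W <- as_scalar_int(scale, "scale")
  if (n < 1L) pdp_error("n_blocks must be >= 1", "pdp_infeasible_params_error")
  if (is.null(eps)) eps <- (W - 1L) %/% (12L * n + 1L)
  eps <- as_scalar_int(eps, "eps")
  if (eps < 1L || 12L * n * eps >= W)
    pdp_error(sprintf("need 0 < 12 * n_blocks * eps < scale (got eps = %d, scale = %d)",
                      eps, W),
              "pdp_infeasible_params_error")
  A1 <- W - (n:1) * eps
  A2 <- (1:n) * eps
  A3 <- (n + 1:n) * eps
  A4 <- (2L * n + 1:n) * eps
  A5 <- W - ((3L * n):(2L * n + 1L)) * eps
  flip <- function() sample(c(TRUE, FALSE), n, replace = TRUE)
  keep_left <- if (is.null(seed)) flip() else withr::with_seed(seed, flip())
  mid <- ifelse(keep_left, A3, W - A3)
  A <- sort.int(c(0L, W, A1, A2, A4, A5, mid))
  if (anyDuplicated(A))
    pdp_error("block construction produced coinciding points; decrease eps",
              "pdp_infeasible_params_error")
  A <- as.integer(A)
  list(points = A, D = delta_set(A))
}
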