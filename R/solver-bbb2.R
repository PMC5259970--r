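#' Memory-minimizing split level for the two-stage solver
#'
#' The two-stage solver runs a breadth-first search down to a split level
#' \eqn{\alpha}, then finishes each surviving node independently. Its
#' worst-case memory is proportional to
#' \eqn{M(\alpha) = n^2 (2^\alpha + 2^{n-\alpha})}: the first stage can hold
#' \eqn{2^\alpha} nodes and each second-stage subtree \eqn{2^{n-\alpha}},
#' every node storing \eqn{O(n^2)} integers. `find_alpha_m` scans
#' \eqn{\alpha = 1, 2, \dots, n} and keeps the first \eqn{\alpha} attaining
#' each strict improvement of \eqn{M(\alpha)}, so ties resolve to the smaller
#' level. For even `n` the minimizer is `n/2`; for odd `n` it is `(n-1)/2`.
#'
#' The argmin is decided by an exact comparison of the exponent pairs of
#' \eqn{2^\alpha + 2^{n-\alpha}} (no floating point), and the reported score
#' is computed with exact big-integer arithmetic, so the result is correct
#' for `n` in the thousands where \eqn{2^n} overflows doubles.
#'
#' @param N Size of the distance multiset; must be triangular, `N = n(n-1)/2`.
#' @return An `alpha_plan`: list with `n`, `alpha_m` (the split level) and
#'   `m_min` (the exact score \eqn{n^2(2^{\alpha_M}+2^{n-\alpha_M})} as a
#'   decimal string).
#' @examples
#' find_alpha_m(45)  # n = 10 -> split level 5
#' @export
find_alpha_m <- function(N) {
  n <- n_from_pair_count(N)
  if (is.na(n))
    pdp_error(sprintf("N = %s is not triangular", format(N)),
              "pdp_nontriangular_error")
  alpha_m <- 1L
  best <- c(1L, n - 1L)
  if (n >= 2L) {
    for (a in 2:n) {
      cur <- c(a, n - a)
      if (pow2sum_less(cur, best)) {
        best <- cur
        alpha_m <- a
      }
    }
  }
  m_min <- big_mul_small(big_add(big_pow2(alpha_m), big_pow2(n - alpha_m)),
                         as.numeric(n)^2)
  structure(list(n = n, alpha_m = alpha_m, m_min = big_to_string(m_min)),
            class = "alpha_plan")
}

# Exact strict comparison 2^p1 + 2^p2 < 2^q1 + 2^q2 via normalized exponent
# pairs: equal exponents collapse to a single higher bit.
pow2sum_less <- function(p, q) {
  p <- norm_pow2_pair(p)
  q <- norm_pow2_pair(q)
  if (p[1L] != q[1L]) return(p[1L] < q[1L])
  p[2L] < q[2L]
}

norm_pow2_pair <- function(p) {
  a <- max(p); b <- min(p)
  if (a == b) c(a + 1L, -1L) else c(a, b)
}

#' @export
print.alpha_plan <- function(x, ...) {
  cat(sprintf("<split plan: n = %d, alpha_M = %d, M_min = %s>\n",
              x$n, x$alpha_m, x$m_min))
  invisible(x)
}

#' Two-stage breadth-first solver (BBb2)
#'
#' Runs [solve_bbb()]'s level-by-level search (with duplicate elimination)
#' only down to the split level `alpha` chosen by [find_alpha_m()], then
#' expands each node of that frontier to completion as an independent
#' breadth-first search, freeing each subtree's frontier before starting the
#' next. This bounds the number of simultaneously held nodes by
#' \eqn{2^\alpha + 2^{n-\alpha}} instead of \eqn{2^n} while returning the
#' identical solution set. Duplicate subproblems are still removed within the
#' first stage and within each subtree, but not across subtrees; any
#' duplicate solutions produced by different subtrees are merged before
#' reporting.
#'
#' @inheritParams solve_bbd
#' @param alpha Optional split-level override; default is the memory-optimal
#'   level from [find_alpha_m()].
#' @return A `pdp_solutions` object.
#' @examples
#' solve_bbb2(c(1, 2, 2, 3, 5, 6, 7, 8, 8, 10))
#' @export
solve_bbb2 <- function(instance, limits = solver_limits(), alpha = NULL,
                       validate = FALSE) {
  inst <- as_pdp_instance(instance)
  limits <- as_solver_limits(limits)
  if (is.null(alpha)) alpha <- find_alpha_m(inst$N)$alpha_m
  alpha <- as_scalar_int(alpha, "alpha")
  if (alpha < 1L) pdp_error("alpha must be >= 1", "pdp_parse_error")

  state <- new_search_state(inst, "bbb2")
  count_node(state, 0L)
  # stage 1: shared BFS down to the split level (solutions reached earlier
  # are emitted by run_bfs on the way)
  frontier <- run_bfs(list(root_node(inst)), inst, state, limits, validate,
                      stop_level = alpha)
  # stage 2: each split-level node becomes the root of its own BFS
  for (node in frontier) {
    run_bfs(list(node), inst, state, limits, validate)
    check_limits(state, limits)
  }
  finish_search(state)
}
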