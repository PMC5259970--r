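#' Resource limits for the solvers
#'
#' All three solvers are exhaustive and the search tree can be exponential in
#' the worst case, so callers may cap the work. `Inf` means unlimited. When a
#' limit is hit the solver signals a condition of class `pdp_limit_error`
#' whose `partial` field holds the solutions found so far, flagged incomplete.
#'
#' @param max_nodes Maximum number of search-tree nodes to materialize.
#' @param max_frontier Maximum number of simultaneous nodes in one
#'   breadth-first level (ignored by the depth-first solver).
#' @param max_seconds Wall-clock budget in seconds.
#' @return A `solver_limits` object.
#' @export
solver_limits <- function(max_nodes = Inf, max_frontier = Inf,
                          max_seconds = Inf) {
  stopifnot(max_nodes > 0, max_frontier > 0, max_seconds > 0)
  structure(list(max_nodes = max_nodes, max_frontier = max_frontier,
                 max_seconds = max_seconds),
            class = "solver_limits")
}

as_solver_limits <- function(x) {
  if (inherits(x, "solver_limits")) x else do.call(solver_limits, as.list(x))
}
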