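#' Depth-first branch-and-bound solver (BBd)
#'
#' The classical exact partial-digest solver: place points one at a time,
#' always taking `y = max(residual)` and trying positions `y` and
#' `width - y`, pruning a placement unless all of its distances to the points
#' already placed are present in the residual pool. The search is exhaustive
#' (it does not stop at the first solution) and does **not** remove repeated
#' subproblems, so identical subtrees may be traversed more than once; only
#' the final reported solution list is deduplicated.
#'
#' The recursion is run on an explicit stack, with the `y` branch explored
#' before the `width - y` branch.
#'
#' @param instance A [pdp_instance()], or a distance multiset / integer
#'   vector, which is validated first.
#' @param limits A [solver_limits()] object.
#' @param validate If `TRUE`, check at every node that the residual equals
#'   `D \ delta_set(X)` (slow; used by the test suite).
#' @return A `pdp_solutions` object: the lexicographically sorted list of all
#'   maps `X` with `delta_set(X) == D`, plus node-count instrumentation.
#' @examples
#' solve_bbd(c(1, 2, 2, 3, 5, 6, 7, 8, 8, 10))
#' @export
solve_bbd <- function(instance, limits = solver_limits(), validate = FALSE) {
  inst <- as_pdp_instance(instance)
  limits <- as_solver_limits(limits)
  state <- new_search_state(inst, "bbd")
  width <- inst$width

  root <- root_node(inst)
  count_node(state, 0L)
  stack <- list(root)
  state$peak_frontier <- 1
  check_every <- 64L
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(node$D$value) == 0L) {
      record_solution(state, node$X)
      next
    }
    children <- expand_node(node, width)
    for (child in children) {
      count_node(state, length(child$X) - 2L)
      if (validate) check_theorem1(child, inst)
    }
    # push in reverse so the y-first child is popped (explored) first
    for (i in rev(seq_along(children)))
      stack[[length(stack) + 1L]] <- children[[i]]
    state$peak_frontier <- max(state$peak_frontier, length(stack))
    if (state$nodes_total %% check_every < 2L || state$nodes_total > limits$max_nodes)
      check_limits(state, limits)
  }
  finish_search(state)
}
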