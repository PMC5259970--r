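#' Breadth-first branch-and-bound solver with duplicate elimination (BBb)
#'
#' Expands the solution tree level by level. Each node at the current level
#' produces at most two children under the same placement and bounding rules
#' as [solve_bbd()], but a child is appended to the next level only if no node
#' with the same point set `X` is already there. Because a node's residual is
#' fully determined by its `X` (the residual is always `D \ delta_set(X)`),
#' equality of `X` implies equality of the whole subproblem, so the pruning is
#' lossless: BBb returns exactly the same solution set as BBd while expanding
#' a (weakly) smaller number of nodes per level.
#'
#' @inheritParams solve_bbd
#' @return A `pdp_solutions` object.
#' @examples
#' solve_bbb(c(1, 2, 2, 3, 5, 6, 7, 8, 8, 10))
#' @export
solve_bbb <- function(instance, limits = solver_limits(), validate = FALSE) {
  inst <- as_pdp_instance(instance)
  limits <- as_solver_limits(limits)
  state <- new_search_state(inst, "bbb")
  count_node(state, 0L)
  run_bfs(list(root_node(inst)), inst, state, limits, validate)
  finish_search(state)
}

# Core BFS loop shared by BBb and both stages of BBb2. `entries` is the
# starting frontier (its nodes are assumed already counted). Solutions are
# recorded into `state`; returns invisibly.
run_bfs <- function(entries, inst, state, limits, validate,
                    stop_level = Inf) {
  repeat {
    # terminal entries become solutions, not frontier members
    live <- list()
    for (node in entries) {
      if (length(node$D$value) == 0L) record_solution(state, node$X)
      else live[[length(live) + 1L]] <- node
    }
    entries <- live
    if (length(entries) == 0L) return(invisible(NULL))
    state$peak_frontier <- max(state$peak_frontier, length(entries))
    level <- length(entries[[1L]]$X) - 2L
    if (level >= stop_level) return(invisible(entries))
    entries <- advance_level(entries, inst, state, limits, validate)
    check_limits(state, limits)
  }
}

# One GenerateNextLevel step: expand every node of `entries`, dedup children
# on their point set within the new level, emit completed maps as solutions.
advance_level <- function(entries, inst, state, limits, validate) {
  width <- inst$width
  seen <- new.env(hash = TRUE, parent = emptyenv())
  nxt <- list()
  for (node in entries) {
    if (length(node$D$value) == 0L) {
      record_solution(state, node$X)
      next
    }
    for (child in expand_node(node, width)) {
      if (validate) check_theorem1(child, inst)
      if (length(child$D$value) == 0L) {
        count_node(state, length(child$X) - 2L)
        record_solution(state, child$X)
        next
      }
      key <- paste(child$X, collapse = " ")
      prev <- seen[[key]]
      if (!is.null(prev)) {
        state$dedup_hits <- state$dedup_hits + 1
        if (validate && !dms_equal(nxt[[prev]]$D, child$D))
          pdp_error("duplicate point sets with differing residuals",
                    "pdp_internal_error")
        next
      }
      count_node(state, length(child$X) - 2L)
      nxt[[length(nxt) + 1L]] <- child
      seen[[key]] <- length(nxt)
      if (length(nxt) > limits$max_frontier)
        pdp_limit_error(sprintf("frontier limit exceeded (> %g nodes in one level)",
                                limits$max_frontier),
                        partial = finish_search(state, complete = FALSE))
    }
  }
  nxt
}

#' Advance a breadth-first frontier by one level
#'
#' Exposes a single `GenerateNextLevel` step of [solve_bbb()]: every node of
#' the frontier is expanded, children whose point set already occurs in the
#' new level are removed, and children with an empty residual are emitted as
#' solutions.
#'
#' @param frontier A list of search nodes, each a list with elements `X`
#'   (sorted point vector) and `D` (residual [dms()]); use
#'   [pdp_root_frontier()] to start.
#' @param instance A [pdp_instance()].
#' @param limits A [solver_limits()] object.
#' @param validate If `TRUE`, assert the residual invariant on every child
#'   and residual equality before any duplicate is dropped.
#' @return A list with elements `frontier` (next-level node list) and
#'   `solutions` (list of completed point sets).
#' @examples
#' inst <- pdp_instance(c(1, 2, 2, 3, 5, 6, 7, 8, 8, 10))
#' lvl1 <- pdp_next_level(pdp_root_frontier(inst), inst)
#' length(lvl1$frontier)
#' @export
pdp_next_level <- function(frontier, instance, limits = solver_limits(),
                           validate = FALSE) {
  inst <- as_pdp_instance(instance)
  limits <- as_solver_limits(limits)
  state <- new_search_state(inst, "bbb")
  nxt <- advance_level(frontier, inst, state, limits, validate)
  list(frontier = nxt, solutions = state$solutions)
}

#' @rdname pdp_next_level
#' @export
pdp_root_frontier <- function(instance) {
  list(root_node(as_pdp_instance(instance)))
}
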