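# Shared machinery for the three branch-and-bound solvers.
#
# A search node is a plain list(X = sorted integer vector, D = dms residual).
# At level k the node holds k + 2 points; the residual always satisfies
# D_node = D_instance \ delta_set(X) (checked when `validate = TRUE`).

root_node <- function(inst) {
  width <- inst$width
  list(X = c(0L, width), D = dms_difference(inst$D, dms(width)))
}

# Remove the multiset of values `x` from D in one pass; NULL when `x` is not
# a sub-multiset (the bounding condition fails).
ms_try_remove <- function(D, x) {
  r <- rle(sort.int(x))
  i <- match(r$values, D$value)
  if (anyNA(i)) return(NULL)
  cnt <- D$count
  if (any(r$lengths > cnt[i])) return(NULL)
  cnt[i] <- cnt[i] - r$lengths
  keep <- cnt > 0L
  new_dms(D$value[keep], cnt[keep])
}

# Expand one node: y = max(residual) may be placed at position y or at
# position width - y (one child only when the two coincide); a child exists
# only if its distances to the current points are available in the residual.
# Children are returned in y-first order.
expand_node <- function(node, width) {
  vals <- node$D$value
  y <- vals[length(vals)]
  cands <- y
  if (width - y != y) cands <- c(y, width - y)
  children <- vector("list", 2L)
  nch <- 0L
  for (cand in cands) {
    newD <- ms_try_remove(node$D, abs(cand - node$X))
    if (!is.null(newD)) {
      nch <- nch + 1L
      children[[nch]] <- list(X = sort.int(c(node$X, cand)), D = newD)
    }
  }
  if (nch == 0L) list() else children[seq_len(nch)]
}

check_theorem1 <- function(node, inst) {
  if (!dms_equal(node$D, dms_difference(inst$D, delta_set(node$X))))
    pdp_error("internal invariant violated: residual != D \\ delta_set(X)",
              "pdp_internal_error")
  invisible(TRUE)
}

# Mutable accumulator for solutions + instrumentation, shared by the solvers.
new_search_state <- function(inst, algorithm) {
  env <- new.env(parent = emptyenv())
  env$inst <- inst
  env$algorithm <- algorithm
  env$sol_keys <- new.env(hash = TRUE, parent = emptyenv())
  env$solutions <- list()
  env$nodes_by_level <- numeric(max(inst$n - 1L, 1L))
  env$nodes_total <- 0
  env$peak_frontier <- 0
  env$dedup_hits <- 0
  env$t0 <- proc.time()[["elapsed"]]
  env
}

count_node <- function(state, level) {
  state$nodes_by_level[level + 1L] <- state$nodes_by_level[level + 1L] + 1
  state$nodes_total <- state$nodes_total + 1
}

check_limits <- function(state, limits) {
  if (state$nodes_total > limits$max_nodes)
    pdp_limit_error(sprintf("node limit exceeded (%g nodes materialized)",
                            state$nodes_total),
                    partial = finish_search(state, complete = FALSE))
  if (is.finite(limits$max_seconds) &&
      proc.time()[["elapsed"]] - state$t0 > limits$max_seconds)
    pdp_limit_error("time limit exceeded",
                    partial = finish_search(state, complete = FALSE))
  invisible(TRUE)
}

# Every emitted solution is re-verified against the original instance before
# it is accepted; duplicates (e.g. from distinct second-stage subtrees) are
# dropped here.
record_solution <- function(state, X) {
  if (!dms_equal(delta_set(X), state$inst$D))
    pdp_error("internal error: candidate solution fails delta_set(X) == D",
              "pdp_internal_error")
  key <- paste(X, collapse = " ")
  if (!is.null(state$sol_keys[[key]])) return(invisible(FALSE))
  state$sol_keys[[key]] <- TRUE
  state$solutions[[length(state$solutions) + 1L]] <- X
  invisible(TRUE)
}

finish_search <- function(state, complete = TRUE) {
  sols <- state$solutions
  if (length(sols) > 1L) {
    m <- do.call(rbind, sols)
    ord <- do.call(order, as.data.frame(m))
    sols <- sols[ord]
  }
  structure(list(
    solutions = sols,
    n = state$inst$n,
    width = state$inst$width,
    algorithm = state$algorithm,
    complete = complete,
    stats = list(
      nodes_by_level = state$nodes_by_level,
      nodes_total = state$nodes_total,
      peak_frontier = state$peak_frontier,
      dedup_hits = state$dedup_hits
    )
  ), class = "pdp_solutions")
}

#' @export
print.pdp_solutions <- function(x, ...) {
  cat(sprintf("<partial digest solutions: %d map%s of %d points (width %d), %s%s>\n",
              length(x$solutions), if (length(x$solutions) == 1L) "" else "s",
              x$n, x$width, x$algorithm,
              if (x$complete) "" else ", INCOMPLETE (limit hit)"))
  for (X in utils::head(x$solutions, 10L))
    cat(" ", paste(X, collapse = " "), "\n")
  if (length(x$solutions) > 10L)
    cat(sprintf("  ... and %d more\n", length(x$solutions) - 10L))
  cat(sprintf("  nodes: %g, peak frontier: %g, duplicate subproblems removed: %g\n",
              x$stats$nodes_total, x$stats$peak_frontier, x$stats$dedup_hits))
  invisible(x)
}

#' Reflect a map about its width
#'
#' Every solution of a partial digest instance has a homometric mirror image
#' `{width - x : x in X}` with the same difference multiset.
#'
#' @param X A point set.
#' @param width Reflection width; defaults to `max(X)`.
#' @export
reflect_points <- function(X, width = max(X)) {
  X <- as_pointset(X)
  as_pointset(width - X)
}
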