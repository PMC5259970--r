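#' Plain-text instance and solution I/O
#'
#' Instances are ASCII files of whitespace-separated integers, multiplicities
#' expressed by repetition; lines whose first non-blank character is `#` are
#' comments. Solutions are written one map per line (ascending
#' space-separated coordinates), sorted lexicographically so that the output
#' of all three solvers is byte-comparable.
#'
#' @param path File path.
#' @return `read_multiset()` returns a [dms()]; `read_points()` an integer
#'   point set.
#' @name pdp_io
NULL

#' @rdname pdp_io
#' @export
read_multiset <- function(path) {
  dms(read_int_tokens(path))
}

#' @rdname pdp_io
#' @export
read_points <- function(path) {
  as_pointset(read_int_tokens(path))
}

read_int_tokens <- function(path) {
  if (!file.exists(path))
    pdp_error(sprintf("file not found: %s", path), "pdp_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tokens <- unlist(strsplit(lines, "\\s+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    pdp_error(sprintf("no data in %s", path), "pdp_empty_input_error")
  bad <- !grepl("^[+-]?[0-9]+$", tokens)
  if (any(bad))
    pdp_error(sprintf("non-integer token '%s' in %s", tokens[bad][1L], path),
              "pdp_parse_error")
  vals <- suppressWarnings(as.integer(tokens))
  if (anyNA(vals))
    pdp_error(sprintf("integer out of range in %s", path), "pdp_parse_error")
  vals
}

#' @rdname pdp_io
#' @param D A distance multiset.
#' @export
write_multiset <- function(D, path) {
  D <- dms(D)
  writeLines(paste(dms_elements(D), collapse = " "), path)
  invisible(path)
}

#' @rdname pdp_io
#' @param X An integer point set (one coordinate per output line).
#' @export
write_points <- function(X, path) {
  writeLines(as.character(as_pointset(X)), path)
  invisible(path)
}

#' @rdname pdp_io
#' @param solutions A `pdp_solutions` object from one of the solvers.
#' @param stats Append per-level node counts and totals as `#` comments.
#' @param path Output file path, or `NULL` to print to stdout.
#' @export
write_solutions <- function(solutions, path = NULL, stats = FALSE) {
  stopifnot(inherits(solutions, "pdp_solutions"))
  lines <- vapply(solutions$solutions, paste, character(1), collapse = " ")
  if (length(lines) == 0L) lines <- "# no solution"
  if (isTRUE(stats)) {
    s <- solutions$stats
    lines <- c(lines,
               sprintf("# algorithm: %s%s", solutions$algorithm,
                       if (solutions$complete) "" else " (incomplete)"),
               sprintf("# nodes per level: %s",
                       paste(s$nodes_by_level, collapse = " ")),
               sprintf("# nodes total: %g", s$nodes_total),
               sprintf("# peak frontier: %g", s$peak_frontier),
               sprintf("# duplicate subproblems removed: %g", s$dedup_hits))
  }
  if (is.null(path)) writeLines(lines) else writeLines(lines, path)
  invisible(path)
}

#' Bundled example instance: TaqI partial digest of the luciferase gene
#'
#' The 28 fragment lengths of a TaqI (TCGA) partial digestion of the 2009 bp
#' luciferase gene, a standard real-data benchmark for partial digest
#' solvers. Solving it yields two homometric 8-point maps, mirror images of
#' each other; the map `{0, 30, 975, 984, 1277, 1377, 1839, 2009}` places the
#' six internal TCGA sites.
#'
#' @return A [dms()] of 28 distances with width 2009.
#' @examples
#' solve_bbb2(luciferase_multiset())
#' @export
luciferase_multiset <- function() {
  read_multiset(system.file("extdata", "luciferase_taqi.txt",
                            package = "partialdigest", mustWork = TRUE))
}
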