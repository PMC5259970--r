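#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases the
#' sequences and turns empty or malformed input into a classed
#' `pdp_malformed_fasta_error`.
#'
#' @param path Path to a FASTA file (one or more records).
#' @return A [Biostrings::DNAStringSet] in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    pdp_error(sprintf("FASTA file not found: %s", path), "pdp_io_error")
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) pdp_error(
      sprintf("malformed FASTA (%s): %s", path, conditionMessage(e)),
      "pdp_malformed_fasta_error")
  )
  if (length(ss) == 0L)
    pdp_error(sprintf("FASTA file contains no records: %s", path),
              "pdp_malformed_fasta_error")
  if (any(Biostrings::width(ss) == 0L))
    pdp_error("FASTA record with empty sequence", "pdp_malformed_fasta_error")
  Biostrings::DNAStringSet(toupper(ss))
}

#' Locate all occurrences of a restriction motif
#'
#' Scans a sequence for exact, case-insensitive matches of `motif` and
#' returns their 0-based start offsets in ascending order. Overlapping
#' occurrences are all reported. Degenerate IUPAC codes in the motif are not
#' interpreted — matching is literal over A/C/G/T.
#'
#' @param seq A character string, [Biostrings::DNAString], or a single-record
#'   [Biostrings::DNAStringSet].
#' @param motif Recognition sequence, e.g. `"TCGA"` for TaqI.
#' @return Integer vector of 0-based offsets (empty when absent).
#' @examples
#' find_motif_sites("ATCGAGGTCGA", "TCGA")  # 1, 7
#' @export
find_motif_sites <- function(seq, motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
    pdp_error("motif must be a single non-empty string", "pdp_parse_error")
  if (!grepl("^[ACGTacgt]+$", motif))
    pdp_error("motif must be over the A/C/G/T alphabet", "pdp_parse_error")
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      pdp_error("pass a single sequence (subset the DNAStringSet first)",
                "pdp_parse_error")
    seq <- seq[[1L]]
  }
  subject <- Biostrings::DNAString(toupper(as.character(seq)))
  hits <- Biostrings::matchPattern(toupper(motif), subject)
  sort.int(as.integer(BiocGenerics::start(hits)) - 1L)
}

#' Simulate a partial digestion
#'
#' Given internal cut positions on a linear molecule of length `L`, a partial
#' digestion produces one fragment for every pair of cut positions (the two
#' molecule ends counting as positions 0 and `L`). The result is the partial
#' digest instance for the map `X = {0} U sites U {L}`: its difference
#' multiset `D` of `n(n-1)/2` fragment lengths, where `n = length(sites) + 2`.
#'
#' Sites must lie strictly inside the molecule; a site at 0 or `L` is
#' rejected rather than merged with an end. The molecule is treated as
#' linear (for circular genomes the pairwise accounting would differ).
#'
#' @param sites Integer vector of distinct cut positions, each in `(0, L)`.
#'   May be empty (uncut molecule).
#' @param L Molecule length in bp.
#' @return A `digest_result`: list with `sites`, `X`, `D`, `n`, `N`.
#' @examples
#' simulate_partial_digest(c(2, 7, 8), 10)
#' @export
simulate_partial_digest <- function(sites, L) {
  L <- as_scalar_int(L, "L")
  if (L < 1L) pdp_error("molecule length must be >= 1", "pdp_parse_error")
  sites <- if (length(sites)) as_pointset(sites) else integer()
  if (length(sites) && (sites[1L] <= 0L || sites[length(sites)] >= L))
    pdp_error("cut sites must lie strictly between 0 and the molecule length",
              "pdp_site_range_error")
  X <- c(0L, sites, L)
  D <- delta_set(X)
  structure(list(sites = sites, X = X, D = D,
                 n = length(X), N = dms_size(D)),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("<partial digest: %d internal sites, n = %d points, N = %d fragments, length %d>\n",
              length(x$sites), x$n, x$N, x$X[length(x$X)]))
  invisible(x)
}

#' Digest a FASTA sequence with a restriction motif
#'
#' Convenience pipeline: read the FASTA, pick one record, locate the motif
#' occurrences, apply a constant cut offset within the recognition site, and
#' simulate the partial digestion. Shifting all cuts by the same offset
#' leaves the fragment-length multiset unchanged except at the molecule ends,
#' so for map reconstruction the offset is usually left at 0 (cut at the
#' motif start).
#'
#' @param fasta Path to a FASTA file.
#' @param motif Recognition sequence (see [find_motif_sites()]).
#' @param cut_offset Cut position within the motif (0-based), added to every
#'   motif start.
#' @param seq_id Optional record name; default is the first record.
#' @return A `digest_result` (see [simulate_partial_digest()]).
#' @export
digest_fasta <- function(fasta, motif, cut_offset = 0L, seq_id = NULL) {
  ss <- read_fasta(fasta)
  if (!is.null(seq_id)) {
    hit <- which(sub("\\s.*$", "", names(ss)) == seq_id)
    if (length(hit) == 0L)
      pdp_error(sprintf("no FASTA record named '%s'", seq_id), "pdp_io_error")
    ss <- ss[hit[1L]]
  } else {
    ss <- ss[1L]
  }
  L <- Biostrings::width(ss)[1L]
  sites <- find_motif_sites(ss, motif) + as_scalar_int(cut_offset, "cut_offset")
  simulate_partial_digest(sites, L)
}
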