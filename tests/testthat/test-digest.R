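write_fasta <- function(...) {
  f <- withr::local_tempfile(fileext = ".fa",
                             .local_envir = parent.frame())
  writeLines(c(...), f)
  f
}

test_that("FASTA reading uppercases records and rejects malformed input", {
  f <- write_fasta(">x", "acgt")
  ss <- read_fasta(f)
  expect_identical(length(ss), 1L)
  expect_identical(as.character(ss[[1L]]), "ACGT")

  f2 <- write_fasta(">a", "ACGTACGT", ">b desc", "TTTT")
  ss2 <- read_fasta(f2)
  expect_identical(sub("\\s.*$", "", names(ss2)), c("a", "b"))

  empty <- withr::local_tempfile(); file.create(empty)
  expect_error(read_fasta(empty), class = "pdp_malformed_fasta_error")
  noheader <- write_fasta("ACGT")
  expect_error(read_fasta(noheader), class = "pdp_malformed_fasta_error")
  expect_error(read_fasta(tempfile("nope")), class = "pdp_io_error")
})

test_that("motif scanning reports every overlapping occurrence, 0-based", {
  expect_identical(find_motif_sites("ATCGAGGTCGA", "TCGA"), c(1L, 7L))
  expect_identical(find_motif_sites("AAAA", "AA"), c(0L, 1L, 2L))
  expect_identical(find_motif_sites("ATCGAGGTCGA", "tcga"), c(1L, 7L))
  expect_identical(find_motif_sites("GGGG", "TCGA"), integer())
  expect_error(find_motif_sites("ACGT", "TCNA"), class = "pdp_parse_error")
})

test_that("partial digestion yields the full pairwise fragment multiset", {
  res <- simulate_partial_digest(c(2, 7, 8), 10)
  expect_true(dms_equal(res$D, dms(worked_example)))
  expect_identical(res$X, c(0L, 2L, 7L, 8L, 10L))

  lucif <- simulate_partial_digest(luciferase_sites, 2009)
  expect_true(dms_equal(lucif$D, luciferase_multiset()))
  expect_identical(lucif$N, as.integer(pair_count(lucif$n)))

  uncut <- simulate_partial_digest(integer(), 7)
  expect_identical(dms_elements(uncut$D), 7L)

  expect_error(simulate_partial_digest(c(0, 3), 10),
               class = "pdp_site_range_error")
  expect_error(simulate_partial_digest(c(3, 10), 10),
               class = "pdp_site_range_error")
  expect_error(simulate_partial_digest(c(3, 3), 10),
               class = "pdp_duplicate_site_error")
})

test_that("digesting a sequence and solving the instance recovers the cut map", {
  # plant TCGA at known offsets in a background without spurious occurrences
  seq <- paste(rep("G", 60), collapse = "")
  for (pos in c(11, 23, 40)) # 0-based motif starts
    substr(seq, pos + 1, pos + 4) <- "TCGA"
  f <- write_fasta(">mol synthetic", seq)
  res <- digest_fasta(f, "TCGA")
  expect_identical(res$sites, c(11L, 23L, 40L))
  expect_identical(res$n, 5L)
  expect_identical(res$N, 10L)
  keys <- canon_sols(solve_bbb2(res$D)$solutions)
  expect_true(paste(res$X, collapse = " ") %in% keys)
  # a constant cut offset shifts the sites but leaves n and N unchanged
  res2 <- digest_fasta(f, "TCGA", cut_offset = 1)
  expect_identical(res2$sites, res$sites + 1L)
  expect_identical(res2$N, res$N)
})
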