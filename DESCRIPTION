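Package: partialdigest
Title: Exact Solvers for the Partial Digest Problem
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs restriction-site maps from partial digestion data.
    Given the multiset of all pairwise fragment lengths between cut sites, the
    package recovers every point set whose difference multiset matches the
    input (the partial digest, or turnpike, problem). Three exact solvers are
    provided: a depth-first branch-and-bound baseline, a breadth-first variant
    that deletes repeated subproblems within each level, and a two-stage
    breadth-first solver that splits the search at a memory-minimizing level.
    Also included are generators for random and adversarial (Zhang-type)
    benchmark instances, an in-silico partial digestion simulator driven by
    FASTA input and a restriction motif, plain-text instance I/O, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
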