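# partialdigest

Exact reconstruction of restriction-site maps from partial digestion data.

In a partial digestion, a single restriction enzyme cuts a linear DNA
molecule incompletely, so that every pair of cut positions (the two molecule
ends included) yields one fragment. The measured data are therefore the
multiset *D* of all *N* = *n*(*n*−1)/2 pairwise distances among *n*
positions, and the reconstruction task — the **partial digest problem**
(PDP, a.k.a. the turnpike problem) — is to find *every* point set
*X* = {*x*₀ < … < *x*ₙ₋₁} with Δ*X* = *D*, where Δ*X* is the multiset of
absolute pairwise differences. The package is aimed at physical-mapping and
algorithm-benchmarking work: it returns all exact integer solutions,
anchored at 0, including the homometric mirror {width − *x*}.

Three exhaustive solvers share one search tree (root {0, width} with
residual *D* \ {width}; a node expands by placing *y* = max(residual) at
position *y* or width − *y*, pruned by the feasibility test
Δ(*y*, *X*) ⊆ residual):

* `solve_bbd()` — depth-first branch and bound (the classical baseline;
  revisits duplicated subtrees),
* `solve_bbb()` — breadth-first with deletion of repeated subproblems
  within each level (sound because a node's residual is determined by its
  point set: residual = *D* \ ΔX),
* `solve_bbb2()` — two-stage breadth-first: deduped BFS to the split level
  α_M minimizing the worst-case memory score
  *M*(α) = *n*²(2^α + 2^(n−α)) (`find_alpha_m()`), then each surviving
  node finished as an independent BFS, capping the frontier ever held.

Around the solvers: benchmark generators (`random_instance()`,
`zhang_instance()` — the adversarial family that forces exponential
depth-first behavior), an in-silico digestion simulator
(`digest_fasta()`, `find_motif_sites()`, `simulate_partial_digest()`),
plain-text instance I/O, search instrumentation (node counts, frontier
peaks, duplicates removed — the hardware-independent substitute for
stopwatch benchmarks), and a CLI (`exec/pdp`: `solve`, `generate`,
`digest`, `alpha`).

## Worked example

The ten-fragment instance *D* = {1, 2, 2, 3, 5, 6, 7, 8, 8, 10}:

```r
library(partialdigest)
solve_bbb2(c(1, 2, 2, 3, 5, 6, 7, 8, 8, 10))
#> <partial digest solutions: 2 maps of 5 points (width 10), bbb2>
#>   0 2 3 8 10
#>   0 2 7 8 10
#>   nodes: 6, peak frontier: 2, duplicate subproblems removed: 1
```

Two homometric five-point maps explain the data — mirror images of each
other about the width 10. The counters show the search effort: six nodes
materialized, never more than two held at once, and one repeated subproblem
(the node {0, 2, 8, 10}, reachable along two paths) deleted; the
depth-first baseline `solve_bbd()` expands that subtree twice (9 nodes).

The bundled real-data instance is the TaqI (TCGA) partial digest of the
2009 bp luciferase gene — 28 fragment lengths:

```r
solve_bbb2(luciferase_multiset())
#> <partial digest solutions: 2 maps of 8 points (width 2009), bbb2>
#>   0 30 975 984 1277 1377 1839 2009
#>   0 170 632 732 1025 1034 1979 2009
#>   nodes: 13, peak frontier: 2, duplicate subproblems removed: 0
```

The first map places the six internal TCGA sites at 30, 975, 984, 1277,
1377 and 1839 on the 2009 bp gene; the second is its mirror.

From a shell, the same computations:

```sh
exec/pdp solve --in instance.txt --algorithm bbb2 --stats
exec/pdp generate --family zd --n 4 --seed 1 --out zd.txt --truth map.txt
exec/pdp digest --fasta genome.fa --motif TCGA --out digest.txt
exec/pdp alpha --n 10        # alpha_M = 5, M_min = 6400
```

See the methods vignette (`vignettes/partial-digest-methods.Rmd`) for the
algorithms, the generator constructions and the package's numerical
choices.

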