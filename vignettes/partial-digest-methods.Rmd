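---
title: "Exact reconstruction of restriction maps from partial digests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact reconstruction of restriction maps from partial digests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partialdigest)
```

## The problem

In a partial digestion experiment a single restriction enzyme cuts a linear
DNA molecule at its recognition sites, but incompletely: by varying reaction
time, every *pair* of cut positions (including the two molecule ends)
contributes one fragment. The data are therefore the multiset $D$ of all
$N = \binom{n}{2}$ pairwise distances among $n$ positions, and the task —
the partial digest problem (PDP), equivalent to the turnpike problem — is to
recover every point set $X = \{x_0 < x_1 < \dots < x_{n-1}\}$ with
$\Delta X = D$, where $\Delta X$ is the multiset of absolute pairwise
differences. Solutions are reported anchored at $x_0 = 0$; the largest
point equals the *width* $\max(D)$, the molecule length. Solutions come in
homometric mirror pairs: if $X$ solves the instance, so does
$\{width - x : x \in X\}$.

The package treats the exact integer PDP only. Distances are non-negative
integers; fractional input is rejected at parse time rather than rescaled,
and there is no tolerance for measurement noise. That restriction is what
makes the multiset algebra — difference with counts clamped at zero,
disjoint union, sub-multiset tests — exact, and it is the regime in which
the solvers are guaranteed to return *all* solutions.

## The search tree and the three solvers

All three solvers explore the same solution tree. The root holds
$X_0 = \{0, width\}$ and the residual pool $D_0 = D \setminus \{width\}$.
A node with point set $X$ and residual $R$ expands by taking the largest
unexplained distance $y = \max(R)$, which must be realized against one of
the two extreme points; the candidate positions are therefore $y$ and
$width - y$ (a single child when the two coincide). A candidate $c$ is kept
only if the bounding condition $\Delta(c, X) \subseteq R$ holds, in which
case the child is $(X \cup \{c\},\ R \setminus \Delta(c, X))$. A node with
an empty residual is a complete map; every emitted map is nevertheless
re-verified against $\Delta X = D$ before it is reported.

Two facts drive the design. First, the residual of any node is determined
by its point set: $R = D \setminus \Delta X$ holds inductively along every
path (the `validate = TRUE` switch of the solvers asserts it at every
node). Second, as a consequence, two nodes with equal point sets are equal
subproblems, so duplicates within a level can be deleted without losing
solutions.

* **`solve_bbd()`** — depth-first branch and bound, the classical baseline.
  It keeps no memory of visited subproblems and may traverse identical
  subtrees repeatedly. The recursion runs on an explicit stack (maps with
  thousands of points would exceed R's call depth), with the $y$ branch
  explored before the $width - y$ branch; the exploration order affects the
  trace only, never the solution set.
* **`solve_bbb()`** — breadth-first, level by level. While building level
  $k+1$, a child whose point set already occurs in that level is dropped
  (`pdp_next_level()` exposes one such step). The duplicate test hashes the
  ascending point tuple only — by the determinism of the residual the pool
  need not enter the key; an associative table replaces a linear list scan,
  an implementation-level change with identical observable behavior.
* **`solve_bbb2()`** — two-stage breadth-first. Stage one runs the deduped
  BFS down to a split level $\alpha$; stage two expands each surviving node
  to completion as an *independent* BFS, freeing each subtree's frontier
  before the next begins. Duplicates across different subtrees are not
  removed (only within each), so identical solutions can be produced twice;
  the final report is globally deduplicated and sorted lexicographically,
  making the output of all three solvers byte-comparable.

### The split level

With at most $2^\alpha$ stage-one nodes and $2^{n-\alpha}$ nodes per
stage-two subtree, each node storing $O(n^2)$ integers, the worst-case
memory score is $M(\alpha) = n^2(2^\alpha + 2^{n-\alpha})$.
`find_alpha_m(N)` recovers $n$ from $N$ by exact integer inversion of
$n(n-1)/2 = N$ (a closed-form start, then integral verification, immune to
floating-point rounding at large $N$) and scans $\alpha = 1, \dots, n$,
keeping the first $\alpha$ at each strict improvement, so ties resolve to
the smaller level: $\alpha_M = n/2$ for even $n$, $(n-1)/2$ for odd $n$.
Because $2^n$ overflows doubles long before the map sizes of interest, the
argmin compares the exponent pairs of $2^\alpha + 2^{n-\alpha}$ exactly
(two powers of two compare by their normalized exponents; no floating
point), and the reported $M_{\min}$ is computed with exact base-$10^7$
limb arithmetic and returned as a decimal string.

```{r alpha}
find_alpha_m(pair_count(10))
```

If the frontier empties before level $\alpha$ (small or infeasible
instances), stage two is simply empty; solutions reached earlier are
emitted on the way. An `alpha` override is accepted for experimentation and
never changes the solution set.

## Instrumentation instead of stopwatch benchmarks

Wall-clock seconds and resident megabytes are hardware-bound, so the
package instruments the search itself: every solver reports nodes
materialized per level and in total, the peak number of nodes held in one
frontier (for the depth-first solver, the peak stack depth), and the number
of duplicate subproblems deleted. These counters are the package's
comparison surface: on adversarial instances the deduped BFS materializes
strictly fewer nodes than the depth-first baseline, and the two-stage
variant's peak frontier never exceeds the single-stage one.

```{r stats}
z <- zhang_instance(3, seed = 1)
c(bbd = solve_bbd(z$D)$stats$nodes_total,
  bbb = solve_bbb(z$D)$stats$nodes_total)
```

## What the generators emulate

**Random instances** (`random_instance(n, max_coord)`) model $n$
restriction sites scattered uniformly: the map is $\{0\}$ plus $n-1$
distinct coordinates drawn without replacement from $1..max\_coord$.
Benchmark practice sets $max\_coord = n q$ with $q \in \{10, 100, 1000,
10000\}$; small $q$ crowds sites together, multiplies repeated distances
and thus repeated subproblems — the regime where duplicate elimination
pays. Anchoring at 0 makes round-trip checks exact: the generating map and
its mirror always appear verbatim in the solver output. The generator does
not model partial cutting efficiency, missing or doubled fragments, or
length-measurement error, so passing round-trips say nothing about noisy
gel data — only about exact reconstruction.

**Adversarial instances** (`zhang_instance(n_blocks, scale, eps)`) realize
the classical worst-case family for depth-first search: five arithmetic
blocks of `n_blocks` points each, placed symmetrically near the ends of the
interval, plus a middle block each of whose points is kept on the left or
reflected to the right by a seeded fair coin (any split yields the
worst-case behavior, so a fair coin is as good as any rule). The published
construction lives on the unit interval with a real step
$\varepsilon < \tfrac{1}{12n}$ (read as $1/(12n)$; the constraint must
scale with $1/n$ for the five blocks to stay disjoint inside the
interval). Since the package is integer-exact, the interval is scaled to an
integer width $W$ (`scale`, default $1000\,n_{blocks}$, the customary
benchmark width) with integer step `eps` (default: largest integer below
$W/(12 n_{blocks} + 1)$); the generator enforces
$12\,n_{blocks}\,eps < W$ and verifies that all $5 n_{blocks} + 2$ points
are distinct. The left/right symmetry keeps both candidate placements
feasible deep into the search, forcing exponentially many — almost all
duplicated — subproblems on the depth-first solver.

## Digestion simulation

`digest_fasta()` reads a FASTA file (Biostrings), scans one record for an
exact, case-insensitive motif (overlapping occurrences all count; IUPAC
degeneracy is not interpreted), and hands the 0-based motif starts to
`simulate_partial_digest()`, which forms $X = \{0\} \cup sites \cup \{L\}$
and its difference multiset. Coordinates are 0-based and the molecule is
treated as linear — the $\binom{n}{2}$ accounting is the linear formula;
circular genomes would need different bookkeeping. The enzyme's cut offset
within its recognition site is exposed as `cut_offset`, but a constant
shift of all internal sites only re-anchors the map, so reconstruction is
unaffected by it; sites falling exactly on a molecule end are rejected
rather than silently merged. The bundled `luciferase_multiset()` fixture is
the TaqI (TCGA) partial digest of the 2009 bp luciferase gene; solving it
returns the published six-site map and its mirror.

## Numerical and degenerate-input choices

* All distance arithmetic is 32-bit-integer exact; widths up to the
  hundreds of millions are safe. Instance validation rejects zeros,
  negatives and non-triangular multiset sizes with classed conditions.
* A candidate placement equal to an existing point produces a 0 in
  $\Delta(c, X)$, which the bounding test rejects automatically (instance
  distances are positive), so duplicate points can never be placed.
* An input whose width has multiplicity above one is accepted as ordinary
  input; the search simply finds no solution.
* Solvers are exhaustive and deterministic; `solver_limits()` caps nodes,
  frontier size or seconds, and a hit limit raises a `pdp_limit_error`
  carrying the partial, explicitly incomplete result.

## Scale of the shipped checks

The test suite exercises: solver-vs-brute-force equality on 200 random
instances with $n \le 6$ and coordinates $\le 30$ (the enumeration oracle
is feasible there); map recovery on 50 random instances with
$n \in 5..12$ and $max\_coord \in \{10n, 1000n\}$; adversarial instances
with 17–27 points (block sizes 3–5), where the node-count and
peak-frontier orderings above are asserted strictly; and the split-level
argmin against an exhaustive scan for all $n \le 64$. These sizes keep the
whole suite under a minute while still covering the regimes — crowded
random maps and symmetric adversarial maps — that differentiate the three
algorithms; the algorithms themselves contain nothing size-specific.

## Limitations

Exact integer distances only — no noise model, no approximate matching; no
double-digest or labeled/probed variants; no cross-level or cross-subtree
memoization; enzyme recognition is a literal A/C/G/T motif. For maps of
many hundreds of points the R-level search loop, not the algorithmics,
becomes the bottleneck.
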