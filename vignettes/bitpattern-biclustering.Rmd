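---
title: "Bit-pattern biclustering of binary matrices: method and design notes"
author: "bitclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-pattern biclustering of binary matrices: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitclust)
```

## The problem

A *bicluster* of a binary matrix $A \in \{0,1\}^{N \times M}$ is a pair
$(I, J)$ of row and column subsets whose induced submatrix is all ones; it is
*maximal* when no further row or column can be added without breaking that
property. In transcriptomics, rows are genes (or proteins) and columns are
conditions (or interaction partners): a maximal bicluster is a candidate
co-expression module or interaction clique. The number of maximal biclusters
grows quickly with size and density, so enumeration speed is the practical
bottleneck — a 200 by 200 matrix at moderate density already carries
thousands of them.

## The algorithm

`bitclust()` enumerates biclusters with a pairwise-AND template strategy over
a 4-bit ("nibble") encoding of the rows:

1. **Encoding.** Each row is packed into $P = \lceil M/4 \rceil$ nibbles,
   most significant bit first; a row shorter than a multiple of four is
   zero-padded on the right. Padded bits are 0 everywhere and therefore can
   never enter a template.
2. **Templates.** Every seed pair $(i, j)$, $i < j$, yields the template
   $\rho_{ij}$, the nibble-wise bitwise AND of the two encoded rows. Its
   *width* is the number of 1-bits; the positions of those bits are the
   candidate column set $J$. A template is processed only if it has not been
   seen before and its width reaches `c_min`.
3. **Row inclusion.** Every remaining row is tested position by position:
   the row survives position $k$ iff the template nibble is a *submask* of
   the row nibble, a constant-time lookup in the precomputed table
   $V = \{V_0, \dots, V_{15}\}$ with $V_0 = \{0\}$ and
   $V_i = \{x \neq 0 : i \wedge x = x\}$. The scan stops at the first failing
   position. Surviving rows, plus the two seeds, form $I$; the bicluster is
   emitted when $|I| \ge$ `r_min`.

Every emitted bicluster is all-ones by construction, and it is maximal in
both directions: rows, because every matching row is collected; columns,
because a column that is 1 across all of $I$ is in particular 1 in both
seeds and hence already in $J$. The converse does not hold — a maximal
bicluster is found only if *some* seed pair's AND equals its column set
exactly. This is the known completeness boundary of pairwise-AND search; the
package's contract is set-equality with the bit-level reference
implementation (`reference_pairwise_and()`), not with full closed-pattern
enumeration (`enumerate_closed()`, which exists to characterize the gap on
small instances).

### The submask table and the average case

The table has 66 memberships in total across its 16 sets
($\sum_{i \ge 1} (2^{\mathrm{popcount}(i)} - 1) + 1 = 66$), so under uniform
nibble contents a single lookup succeeds with probability $66/256 \approx
1/4$. If a fraction $p$ of cells are 1, then conditional on a template
column (both seeds 1 there) an independent row survives that column with
probability $p$: the number of rows surviving successive template columns
decays geometrically, $N, Np, Np^2, \dots$, which is what makes the expected
work per template linear in $N$ rather than $N \times M$.
`retention_profile()` measures these survivor ratios directly, and
`comparison_stats()` records exact per-template lookup counts, whose
envelope is $(N-2) \cdot P$ (all-ones worst case) down to $(N-2) + (P-1)$
(a first position that rejects everything but one row).

One definitional subtlety: the formal sets $V_i$, $i \ge 1$, range over
nonzero $x$ only, which would make a template nibble of 0 fail against every
row. A zero template nibble carries no constraint (0 is a submask of
everything), so the membership predicate used by the search treats it as
universally contained. Without this extension no row could ever join a
template with an empty nibble, which would be plainly wrong.

## Modes and parameters

* `r_min`, `c_min` (rows/columns, minimum 2 and 1): size floor for emitted
  biclusters. **base mode** pins both to 2, which yields the complete
  pairwise-AND-reachable maximal set; user-supplied values are coerced back
  with a warning, since any other setting changes the semantics from
  "maximal enumeration" to "filtered enumeration".
* **flex mode** honours stricter minimums and adds two optional filters:
  `remove_symmetric` (on square matrices with a shared label space, each
  bicluster $(I, J)$ has a transpose twin $(J, I)$; the filter keeps the
  lexicographically smaller member of each pair, and self-symmetric clusters
  are kept) and `top_k` (retain the $k$ largest by area, off by default).
  Flex mode is described operationally in the literature as "fewer, larger,
  filtered"; anything beyond explicit parameters and symmetric removal would
  be an invented prior, so the package exposes only these knobs.
* `skip_sparse_seeds`: rows with fewer than `c_min` ones cannot seed a wide
  enough template, so such pairs are skipped before ANDing. This is provably
  output-equivalent (such templates would be discarded by the width check)
  and is unit-tested as such.
* Template bookkeeping: a template is marked "seen" as soon as any pair
  produces it, *including* templates below `c_min`. Whether sub-width
  templates should be marked is not observable in the output (they are
  discarded either way); marking them avoids re-deriving the same discard.

Determinism: seed pairs iterate in lexicographic order over the input row
order, emission follows discovery order, and no randomness is consumed
anywhere in the search, so identical inputs give identical outputs.

## Binarization of expression data

Real-valued expression matrices enter through `binarize()`:

* `threshold` — global cutoff $\tau$ (cell is 1 iff value $> \tau$),
* `quantile` — per-gene cutoff at quantile $q$ (default 0.5),
* `ltmg` — a deliberately simplified per-gene two-component Gaussian
  mixture: values are censored upward at a detection floor (default: the
  gene's smallest positive value) as a cheap approximation of
  left-truncating dropout mass, a two-component EM is run with a
  deterministic median-split initialisation (so a seed is recorded but not
  consumed), and a cell is called 1 when the posterior of the higher-mean
  component exceeds 0.5. Genes with degenerate variance or collapsed
  components fall back to the quantile rule, recorded per gene in the
  `binarize` attribute.

This is *not* a faithful left-truncated mixture model with per-gene model
selection — binarization is an imported preprocessing step here, not the
contribution — and no attempt is made to reproduce any specific published
binary matrix bit for bit. On well-separated synthetic mixtures
($\mu = 0$ vs $4$, $\sigma = 1$, $n = 200$ conditions) the EM assigns at
least 95% of cells to their generating component, which is the fidelity
level the tests pin down.

## Synthetic benchmark generators

Three families mirror the standard evaluation layouts, and every generator
is seed-reproducible (one derived RNG stream per matrix, so suites
regenerate element-wise):

* `gen_density_matrix(n, m, density, seed)` — i.i.d. Bernoulli cells;
  density grids such as 5–50% in steps of 5 are a one-liner.
* `gen_scaling_suite()` — square matrices 50 to 500 in steps of 50, ten
  densities (10–100%) per group.
* `gen_implanted()` / `gen_implant_suite()` — all-ones blocks placed along
  the diagonal with a controlled number of shared rows/columns between
  consecutive implants, plus an exact ground-truth record. Diagonal
  chaining with shared corners is the conventional implant geometry and
  keeps the expected results analytically checkable.

For the default implant suite the block side is $s = 10 + d/10$ and
consecutive blocks share $o = d/10$ rows and columns at overlap degree
$d\%$, so the matrix is $(100 + d/10)$ square — the same 100 by 100 through
110 by 110 progression the benchmark family uses. (Deriving the shared count
as $\lfloor d/100 \cdot \min(\text{sizes}) \rfloor$, which `gen_implanted()`
does when no explicit `shared` is given, produces different dimensions for
$d \ge 50$; the suite therefore passes `shared` explicitly.) Background
density defaults to 0 for implant suites — recovery statements are about
structure, not noise robustness. With zero background and at most one shared
row between neighbours (overlap 0% or 10%), the enumeration provably returns
exactly the implants, so relevance and recovery are both 1; from 20% overlap
upward, pairs of shared rows form genuine extra maximal biclusters spanning
the union of two column blocks, and relevance drops by exactly the
Jaccard penalty of those union clusters.

What the generators do *not* emulate: correlated noise, row/column
popularity effects (hub proteins, batch structure), and real dropout
patterns. Passing recovery tests on implants therefore demonstrates
correctness of the enumeration and scoring machinery, not robustness on
noisy biological data.

## Evaluation metrics

`match_score(found, reference)` is the mean, over `found`, of each
bicluster's best Jaccard similarity in `reference`; `relevance_recovery()`
reports both directions against a ground truth (relevance = found vs truth,
recovery = truth vs found), which is also why the report carries both — the
score is not symmetric. Collections are treated as sets (exact duplicates
collapse). Two scopes are offered because published evaluations are
ambiguous about which they use: `rows` (Jaccard on row sets — the gene-level
score; the default) and `rows_and_cols` (Jaccard on cell sets). Reports name
their scope. Degenerate conventions: an empty found set scores 0; empty
biclusters are rejected.

## Oracles and what "correct" means here

Correctness is anchored by brute force on small instances:

* `reference_pairwise_and()` — the same contract, computed bit-level with no
  encoding, no lookup table; set-equality with `bitclust()` on hundreds of
  random instances is the repository's central test.
* `verify_maximal()` — exhaustive row/column extension check.
* `enumerate_closed()` — all maximal all-ones submatrices via row-subset
  closure ($2^N$), to verify the search output is a subset and to expose
  the patterns pairwise AND can miss.

Size caps (64 for the reference, 20 for closed enumeration) are arguments,
not constants, and the operations refuse larger inputs explicitly.

## Numerical and engineering choices

* The inner enumeration is compiled (Rcpp): the work is a tight loop over
  row pairs and nibble comparisons, the kind of kernel R-level code cannot
  express efficiently. Comparison counting (one submask lookup = one
  comparison) is exact, not sampled, and is defined at nibble granularity;
  the geometric-decay property, not any absolute constant, is the tested
  contract.
* Problem sizes in the tests and the acceptance script: oracle equivalence
  on 100 random 30 by 30 matrices (densities 10–50%), maximality on 200
  random 15 by 15 matrices, closed-pattern containment on 10 by 10, scaling
  on the 50–300 slice of the scaling suite. These sizes exercise every code
  path while keeping brute-force oracles comfortably tractable.
* Duplicate rows are retained as distinct bicluster members — collapsing
  them would silently change `r_min` semantics on data with replicated
  probes.
* Ties and ordering: all serialized outputs sort labels; canonical
  comparisons use sorted `"rows|cols"` keys so set equality is independent
  of discovery order.

## Limitations

* Completeness: biclusters whose column set is not the exact AND of any row
  pair are not found (inherent to the strategy; quantified by
  `enumerate_closed()` on small instances). Single-row biclusters are never
  emitted.
* The simplified mixture binarization has no model selection over component
  counts and approximates truncation by censoring; it is a pragmatic
  default, not a reimplementation of the full truncated-mixture model.
* The symmetric-removal filter assumes the row and column label spaces
  coincide; on anything else it is an identity pass with a warning.
* Enumeration output size grows roughly with the number of distinct row
  pairs; on large dense matrices memory for the result list, not search
  time, becomes the practical limit.
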