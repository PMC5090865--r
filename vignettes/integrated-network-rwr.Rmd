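---
title: "Ranking ADR-related proteins by random walk on an integrated network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking ADR-related proteins by random walk on an integrated network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inpadr)
```

## The problem

Adverse drug reactions (ADRs) often arise from drugs engaging off-target
proteins. Knowing which proteins can elicit a given ADR helps explain
observed drug--ADR pairs and supports preclinical safety screening, but
experimentally verified protein--ADR relations are scarce. `inpadr`
prioritizes candidate proteins for a query ADR by propagating information
through a heterogeneous network that combines three complementary signals:

* a **PPI layer** `A` (`n x n`): confidence-weighted protein--protein
  interactions, weights in `[0, 1]`;
* an **ADR similarity layer** `C` (`m x m`): two ADRs are similar when
  overlapping sets of drugs cause them, quantified by the Jaccard index of
  their drug sets, `|D_i ∩ D_j| / |D_i ∪ D_j|`;
* a **bipartite layer** `B` (`n x m`): known (gold-standard) protein--ADR
  relations.

The integrated adjacency is the block matrix `W = [[A, B], [B', C]]`. The
working hypothesis is modular co-localization: proteins that elicit
similar ADRs tend to interact with one another, so proximity to an ADR's
known proteins -- measured through all three layers at once -- is evidence
of an unobserved relation.

## The walk

**Transition model.** Rows of the transition matrix
`M = [[M_PP, M_PA], [M_AP, M_AA]]` are normalized within blocks and
coupled by the jumping probability `lambda`. For a protein `i` with both
PPI edges and known ADR links,

    M_PP[i, j] = (1 - lambda) * A[i, j] / sum_k A[i, k]
    M_PA[i, j] = lambda * B[i, j] / sum_k B[i, k]

and symmetrically for ADR rows using `C` and `B'`. Intra-layer moves are
weighted by edge weight (a confidence-0.9 interaction receives proportionally
more traffic than a 0.2 one); cross-layer moves are uniform over the
node's bipartite links. Edge cases are resolved so the walker never
invents edges:

* a node with no bipartite links keeps all its mass in its own layer at
  every `lambda` (it simply cannot jump);
* a node whose only links are bipartite sends all its mass across when
  `lambda > 0`; at `lambda = 0` cross-layer movement is impossible by
  definition, so such a row is left empty (dangling);
* fully isolated nodes have all-zero rows.

Row normalization makes the model invariant to any global rescaling of the
weights, which the test suite asserts.

**Seeds.** A query is one focus ADR plus its known related proteins. The
initial distribution places `eta` on the ADR node and `1 - eta` uniformly
over the seed proteins; at `eta = 0.5` the two layers carry equal
importance, larger `eta` biases the walker toward the ADR similarity
layer. When an ADR has no known proteins left (a single-relation ADR under
leave-one-out), all mass goes to the ADR node -- the walk then reaches
proteins only through ADR similarity, which is precisely the situation a
PPI-only walk cannot handle.

**Iteration.** The walk with restart iterates

    p_{t+1} = (1 - r) * M' p_t + r * p_0

until the L1 change falls below `tol` (default `1e-10`, capped at 1000
iterations; with restart `r` the iteration contracts at rate `(1 - r)` per
step, so convergence takes a few dozen iterations at the defaults).
Probability that flows into dangling rows is redistributed proportionally
to `p_0` before the restart term, keeping `sum(p) = 1` at every step
without altering the network. Non-convergence returns the last iterate
with a warning rather than an error. The stable vector's protein block,
restricted to candidates (all proteins not already known for the ADR),
gives the ranking; ties take their average rank, the Mann--Whitney
consistent midrank, and rows are ordered by rank then id so identical
inputs produce identical output.

Defaults are `r = 0.7`, `lambda = 0.5`, `eta = 0.5`, following common
practice for restart walks on heterogeneous biological networks; the
cross-validated AUC is nearly flat in `r` (the acceptance suite bounds the
spread over `r` in `{0.3, 0.5, 0.7, 0.9}` by 0.05), while `lambda` and
`eta` are the scientifically meaningful dials (layer coupling and seed
balance).

## Evaluation

Leave-one-out cross-validation holds out each gold relation in turn,
removes that edge from `B` *before* seeding (asserted in code), reseeds
from the ADR and its remaining proteins, and records the rank of the test
protein among the candidates. Candidate sets differ in size across ADRs,
so folds are pooled on the normalized rank

    nr = (rank - 1) / (n_candidates - 1)

which is the fraction of competitors the test protein lost to: `nr = 0`
means it beat every other candidate, `nr = 1` means it lost to all. The
ROC sweeps every distinct normalized rank as a threshold; sensitivity is
the fraction of folds at or below the threshold, and 1 - specificity
equals the threshold itself (the pooled fraction of candidates ranked
above it). The curve is the exact step polygon, so its trapezoidal area
equals the Mann--Whitney statistic of the normalized ranks against a
uniform reference -- a perfect ranking scores exactly 1 and uniform ranks
score 0.5, and the suite checks the two routes agree to `1e-10`. We use
`(rank - 1) / (n - 1)` rather than `rank / n` precisely because the latter
caps the AUC of a perfect ranking at `1 - 1/n` and breaks the
Mann--Whitney identity.

Pooling across ADRs treats all folds exchangeably on the normalized
scale; this is one consistent reading of pooled sensitivity/specificity
when candidate sets differ per query, and it is the one this package
documents and tests.

A technical symmetry is worth recording: on a self-dual fixture whose
protein and ADR layers are the same weighted graph and whose bipartite
layer equals that graph's adjacency, exchanging the layers maps the walk
with seed split `eta` onto the walk with `1 - eta` with the two blocks of
the stable vector exchanged (tested to machine precision). This exchanges
*protein* ranks under one `eta` with *ADR* ranks under the other, so it
does **not** make the protein-only cross-validated AUC a symmetric
function of `eta`; the package tests the exact vector-level symmetry
rather than an AUC identity that the construction does not imply.

## Comparison methods

**Hypergeometric enrichment.** Each candidate protein is scored by the
over-representation of the focus ADR's known proteins among its PPI
neighbors: with neighborhood size `s`, overlap `k`, ADR protein-set size
`K` and population `N` (all indexed proteins), the score is the exact
upper tail `P(X >= k)` (computed via `stats::phyper`; the test suite
verifies it against exhaustive enumeration of all draws for `N <= 12`).
Ranking is by ascending p-value. This neighborhood-vs-protein-set
contingency is a reconstruction of a network-based enrichment baseline:
the original drug-mediated Fisher construction needs per-drug target
tables that the integrated network does not retain, so the PPI
neighborhood reading is adopted and documented as such rather than
asserted as the historical procedure.

**PPI-only walk.** The same restart walk run on the row-normalized PPI
layer alone, seeded uniformly on the ADR's remaining known proteins. It
requires at least one remaining seed, so its gold standard keeps only
ADRs with two or more related proteins ([filter_gold_for_rwr()]). Setting
`lambda = 0, eta = 0` in the integrated walk reproduces it exactly (the
suite checks agreement to `1e-10`), which pins down the degeneration
structure of the model.

## The synthetic fixture

Real inputs at scale (STRING-like interaction snapshots, SIDER-like
drug--ADR tables, curated gold standards) are external databases, so the
package ships a generator that emulates their *structure* at desk scale:

* **PPI**: planted-partition graph, 200 proteins in 5 modules,
  within/between edge probabilities 0.35 / 0.02, weights uniform on
  `[0.3, 1]`. The planted-partition topology is primary because modular
  co-localization is the method's assumption; a preferential-attachment
  option echoes the heavy-tailed degree distributions of real interaction
  networks, for robustness checks only.
* **Drugs**: 120 drugs split into module pools; each of 40 ADRs draws on
  average 8 drugs, 90% from its module pool -- inducing high within-module
  Jaccard similarity (asserted over 10 seeds).
* **Gold standard**: on average 3 relations per ADR (about 115--125
  total); each related protein comes from the ADR's module with
  probability `signal` (default 0.9), else uniformly from connected
  proteins.

The per-ADR scale (about 3 proteins per ADR, a few hundred relations
overall) mirrors sparse curated gold standards in this domain. Counts use
`1 + Poisson(mean - 1)` so every ADR has at least one relation; a
`fixed_counts` switch makes them exact for tests. Fixed seeds give
byte-identical files.

What the fixture does **not** emulate: literature-driven
ascertainment bias (real gold standards over-sample well-studied
proteins), correlated annotation noise, drug polypharmacology structure
beyond module pools, and the true size (thousands of proteins, hundreds
of thousands of interactions). Passing the planted-signal tests shows the
machinery recovers modular co-localization signal when present and finds
nothing in permuted labels; it does not certify real-data AUC levels,
which depend on the databases used.

## Numerical and design choices

* STRING-style integer confidence scores are supported via
  `weight_scale = "string_0_999"` (divide by 1000); the raw `[0, 1]` scale
  is the default since the input scale cannot be inferred reliably from
  data.
* Zero-weight PPI records are non-edges and are dropped; negative or
  non-numeric weights are errors. Duplicate undirected edges collapse by
  maximum weight; self-loops are dropped with a warning.
* Relations naming proteins outside the PPI index are dropped with a
  warning by default (only networked proteins can be ranked); a strict
  error mode exists.
* Asymmetric inputs to the assembler are symmetrized by elementwise
  maximum with a warning; diagonals are forced to zero.
* Convergence: L1 tolerance `1e-10`, max 1000 iterations; the dense
  closed-form solve `r (I - (1 - r) M')^{-1} p_0` (with dangling rows
  replaced by the restart distribution) is used as an independent oracle
  in the tests, to `1e-8` on random instances.
* Ties everywhere use midranks; residual ordering is lexicographic by
  protein id, making every ranking deterministic.

Validation problem sizes: random heterogeneous networks up to ~55 nodes
for the oracle-equivalence checks, the 200-protein fixture for
cross-validation properties (a full LOOCV runs in about a second), 10
permutation seeds for the null band, 5 generator seeds for the
method-ordering checks. These sizes make the planted signal and its
absence cleanly separable while keeping the whole suite fast.

## Limitations

* One ADR per query; batch use loops single queries.
* ADR similarity is drug co-occurrence Jaccard only -- no semantic
  (ontology-based) similarity, and rare ADRs with few recorded drugs get
  noisy similarities.
* The enrichment baseline is a documented reconstruction (see above).
* Performance numbers on synthetic fixtures characterize the algorithm,
  not any real database snapshot.
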