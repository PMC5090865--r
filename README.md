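# inpadr

Prioritization of proteins underlying adverse drug reactions (ADRs) by
random walk with restart on an integrated heterogeneous network.

## What problem this solves

ADRs frequently arise from drugs engaging off-target proteins, but
experimentally verified protein–ADR relations are scarce. Given

* a confidence-weighted protein–protein interaction (PPI) network,
* a drug–ADR table (from which ADR–ADR similarities are computed as the
  Jaccard index of the two ADRs' drug sets), and
* a sparse gold standard of known protein–ADR relations,

`inpadr` builds the integrated network with block adjacency
`W = [[A, B], [Bᵀ, C]]` (PPI layer `A`, bipartite relations `B`, ADR
similarity `C`) and ranks candidate proteins for a query ADR by the
stable probability of a random walk with restart,

```
p_{t+1} = (1 − r) Mᵀ p_t + r p_0
```

where `M` is the block transition matrix with per-step probability
`lambda` of crossing between the protein and ADR layers, and the seed
distribution `p_0` places weight `eta` on the query ADR and `1 − eta`
uniformly on its known proteins. Defaults: `r = 0.7`, `lambda = 0.5`,
`eta = 0.5`. Because the ADR node itself is a seed, the method still
works for ADRs with a single known protein, where a PPI-only walk cannot
be evaluated.

The package also provides leave-one-out cross-validation with exact
ROC/AUC (threshold sweep over normalized ranks; provably equal to the
Mann–Whitney statistic), two comparison methods (hypergeometric
neighborhood enrichment, PPI-only random walk), and a planted-partition
synthetic-data generator so everything is testable without external
database downloads. Audience: computational biologists working on drug
safety / network-based target prioritization.

## Worked example

```r
library(inpadr)

# a synthetic study fixture: 200 proteins in 5 modules, 40 ADRs, 120 drugs,
# planted module signal 0.9 (see the vignette for what this emulates)
truth <- generate_synthetic(synthetic_config())
net <- build_network(truth$ppi, truth$relations, truth$drug_adr)
net
#> Integrated protein-ADR network
#>   proteins: 200 (1690 PPI edges)
#>   ADRs:     40 (186 similarity edges)
#>   known protein-ADR relations: 115

# rank candidate proteins for one ADR
res <- inpadr_rank(net, "ADR007")
top_k(res, 5)
#> Protein ranking for ADR 'ADR007' (197 candidates)
#>   protein       score rank
#> 1   P0181 0.003702235    1
#> 2   P0162 0.003319567    2
#> 3   P0176 0.003155254    3
#> 4   P0190 0.003101552    4
#> 5   P0177 0.002891446    5
```

`score` is the stable probability of finding the walker at that protein
(proximity to the ADR's seed set through all three layers); `rank` is its
position among the 197 candidates (proteins not already known for
ADR007). Leave-one-out cross-validation over all 115 gold relations:

```r
loocv(net)
#> LOOCV [inpadr]: 115 folds (0 failed/skipped), AUC = 0.8069
#>   params: r = 0.7, lambda = 0.5, eta = 0.5
loocv(net, method = "hypergeometric")
#> LOOCV [hypergeometric]: 115 folds (0 failed/skipped), AUC = 0.6707
#>   params: r = 0.7, lambda = 0.5, eta = 0.5
```

The integrated walk recovers the planted signal (AUC ≈ 0.81) and clearly
beats the enrichment baseline, mirroring the qualitative ordering the
method was designed to achieve.

Real data are used the same way: `build_network("ppi.tsv",
"relations.tsv", drug_adr = "drug_adr.tsv", weight_scale =
"string_0_999")` reads tab-separated edge lists (gzip supported; see
`?read_ppi` for formats). A thin command-line front end with `simulate`,
`build`, `rank` and `loocv` subcommands is installed at
`system.file("cli", "inpadr.R", package = "inpadr")`.

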