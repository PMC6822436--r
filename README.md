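# pcgkit

Detection, simulation and evaluation of **phylogenetic core groups (PCGs)**
in microbial communities.

## The problem

16S amplicon surveys of the "core microbiome" usually ask which OTUs, or
which named taxa, occur in every sample of an ecosystem. Both framings miss
the natural unit: selection that acts on phylogenetically conserved traits
maintains *clades* — of whatever depth the trait conservation dictates — in
every instance of the ecosystem, even while the particular member occupying
the niche churns neutrally from sample to sample. `pcgkit` is for microbial
ecologists who want to find those units, and to test whether a community is
consistent with phylogenetically constrained assembly at all.

## What it computes

Given a rooted phylogeny over taxa and a samples × taxa count matrix
`X`, define the pooled abundance of tree node `v` in sample `s` as
`A(s, v) = Σ_{t ∈ leaves(v)} X[s, t]`. Node `v` is **present** in `s` when
`A(s, v) ≥ min_count` and `A(s, v) / Σ_t X[s, t] ≥ min_relabund`, and
**core** when it is present in at least `⌈prevalence · S⌉` of the `S`
samples. The PCGs are the **minimal core nodes** — core nodes with no core
child. Pooling before thresholding makes coreness monotone rootward, so
PCGs are pairwise disjoint and every core lineage is reported at its finest
supported resolution; detection is one postorder pass, `O(S·N)`.

Around the detector:

* **Ladder mode** — `p_distance_matrix()` + `ladder_dendrogram()` build an
  agglomerative dendrogram whose node heights are merge distances, so one
  tree embodies the whole continuum of OTU similarity thresholds;
  `cut_dendrogram()` recovers any flat clustering exactly.
* **Statistics** — `ses_mpd()` (standardized effect size of mean pairwise
  patristic distance against a label-shuffle null; negative = clustering)
  and `pcg_turnover()` (1 minus the modal frequency of each group's
  per-sample dominant member).
* **Simulator** — `simulate_dataset()` generates communities under the
  phylogenetically constrained assembly model: phylo-niches bound to
  clades, non-phylo-niches bound to scattered sets, neutral
  winner-take-all or guild lotteries within niches, patch pooling with
  Dirichlet weights, multinomial read depth, alternative regimes — with
  full ground truth.
* **Evaluator** — `match_pcgs()` / `recovery_experiment()` score detected
  groups against planted clades (greedy one-to-one Jaccard matching,
  exact and graded recall, precision).

See the vignette (`vignettes/pcg-framework.Rmd`) for the model, parameter
meanings and design choices.

## Worked example

```r
library(pcgkit)

cfg <- sim_config(n_taxa = 32, k_phylo = 2, k_nonphylo = 1, n_samples = 10,
                  patches_per_sample = 1, depth = 5000, seed = 7)
sim  <- simulate_dataset(cfg)
pcgs <- find_pcgs(sim$tree, sim$table)
pcgs
#> pcg_set: 2 PCG(s) across 10 sample(s), 32 taxa
#>   pcg_1: 5 taxa, depth 0.4012, prevalence 1 [t0002,t0003,t0012,t0013,...]
#>   pcg_2: 5 taxa, depth 0.3064, prevalence 1 [t0014,t0015,t0016,t0024,...]

pcg_summary(pcgs, sim$table, sim$tree)
#> pcg_summary: 2 PCG(s), mean community coverage 0.8804
#>   pcg_id n_taxa     depth prevalence mean_pooled_relabund
#> 1  pcg_1      5 0.4012263          1              0.10554
#> 2  pcg_2      5 0.3063749          1              0.77482

pcg_turnover(pcgs, sim$table)[, 1:4]
#>   pcg_id S_effective f_mode turnover
#> 1  pcg_1          10    0.6      0.4
#> 2  pcg_2          10    0.4      0.6

match_pcgs(pcgs, sim$truth)
#> recovery_report [regime_1]: recall(tau=1) 1.000, exact recall 1.000, precision 1.000
```

Both planted clades were recovered exactly (`jaccard = 1`); they are present
in all 10 samples (`prevalence 1`) at depths 0.31–0.40 on the unit-height
tree, together holding 88% of the reads, while their internal dominant
member switches across samples (turnover 0.4 and 0.6) — the signature of
neutral within-niche lotteries. `ses_mpd(sim$table, sim$tree,
permutations = 999, seed = 7)` gives a mean SES of −0.70: the community is
phylogenetically clustered.

A command-line interface wrapping the same functions is installed at
`exec/pcgkit` (subcommands `detect`, `simulate`, `signal`, `evaluate`,
`recover`).

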