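# deathnet

Rank-based interaction-perturbation analysis of cell-death interaction
networks for tumor subtyping, subtype propagation, and prognostic marker
screening.

## The problem

Molecular subtypes called directly on expression snapshots travel poorly
across platforms and cohorts. A more portable signal is the *relative
ordering* of genes within each sample, read out over the edges of a
biological network. For a pathway-restricted interaction network (cell
death pathways here), each sample is reduced to per-edge **delta ranks**
— for edge *(a, b)*, `d = rank(a) − rank(b)` within the sample — and
compared with a normal-tissue **benchmark** (the average delta rank over
normal samples). The resulting **interaction-perturbation matrix**

```
p(e, j) = d(e, j) − b(e)
```

is near zero for normal-like samples and strongly non-zero for tumors,
and is exactly invariant to any monotone per-sample transform of the
expression values.

On this matrix the package:

- selects representative edges (tumor-vs-normal Wilcoxon ∩ high tumor SD,
  top-6000 lists),
- discovers subtypes by consensus clustering (PAM on 1 − Spearman,
  resampling 0.8 × 1000, CDF delta-area choice of K),
- derives disjoint subtype signature gene sets and propagates subtypes to
  new cohorts by nearest-template prediction (cosine distance,
  permutation FDR < 0.2),
- scores samples or cells against gene sets by ssGSEA,
- and screens subtype markers across cohorts: ROC AUC > 0.9 and
  univariate Cox p < 0.05 with HR > 1 in *every* cohort, ranked by mean
  Harrell's C-index, validated by median-split Kaplan–Meier and IHC
  H-scores.

A synthetic-data module generates a scale-free network, cohorts with
planted subtypes, subtype-linked exponential survival, and a planted
marker gene, so the full pipeline is testable end to end without any
download.

## Worked example

```r
library(deathnet)

cfg <- sim_config(seed = 1)                       # reference conditions
net <- generate_network(cfg$n_genes, cfg$attach_m, cfg$seed)
A   <- simulate_cohort(cfg, network = net, cohort = "A", sample_seed = 1)

scale_free_fit(net)$r
#> [1] -0.9635645

ip <- interaction_perturbation(A$expr, A$annotation$condition, net)
ps <- perturbation_summary(ip$pmat, A$annotation$condition)
round(ps$condition_mean_abs, 1)
#> normal  tumor
#>   49.3  135.4

sel <- select_features(ip$pmat, A$annotation$condition)   # clamps to 1196
tumor <- A$annotation$condition == "tumor"
cc <- consensus_cluster(ip$pmat[sel$selected_edges, tumor],
                        k_range = 2:10, iters = 250, seed = 102)
cc$recommended_k
#> [1] 4
```

The degree distribution of the generated network is scale-free
(log–log fit r ≈ −0.96); tumors are ~2.7× more strongly perturbed than
normals; the CDF delta-area rule recovers the four planted subtypes
(adjusted Rand index 1.0 against the planted labels at these
conditions). Deriving signatures from the discovered subtypes and
running the marker screen over three validation cohorts returns exactly
one gene passing AUC > 0.9 and the Cox filter in all cohorts — the
planted marker — whose pooled median-split log-rank p is ~1e−05.

The same steps, file-driven and narrated, live in `analysis/01…06`:

```sh
Rscript analysis/01_simulate.R            # inputs under results/data/
Rscript analysis/02_network_perturbation.R
Rscript analysis/03_subtypes.R
Rscript analysis/04_signatures_ntp.R
Rscript analysis/05_gene_set_scores.R
Rscript analysis/06_marker_screen.R
```

## Layout

```
R/                 package code: syndata, netbuild, perturb, subtype,
                   ntp, enrich, survstats, biomarker, pipeline (run_all)
analysis/          numbered narrative drivers over the package
scripts/           acceptance.R (headline quantities as JSON)
tests/testthat/    unit, property and end-to-end tests with
                   brute-force oracles
vignettes/         methods vignette: model, parameters, design choices
```
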