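---
title: "Interaction-perturbation analysis of cell death networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-perturbation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Bulk tumor transcriptomes are noisy in absolute expression but remarkably
stable in *relative* expression: the within-sample ordering of genes.
`deathnet` exploits this by comparing samples not gene-by-gene but
edge-by-edge over a pathway-restricted background interaction network
(here, cell-death pathway genes connected by confidence-filtered
interactions).

For sample $j$, each gene $g$ receives its within-sample rank $r_{gj}$
(ascending, 1 = lowest expression; ties get average ranks).  For an edge
$e = (a, b)$ in canonical orientation, the **delta rank** is

$$d_{ej} = r_{aj} - r_{bj}.$$

Gene interactions are conserved in normal tissue, so the normal samples
define a per-edge **benchmark** $b_e$: the average of $d_{ej}$ over the
normal samples.  The **interaction-perturbation** of edge $e$ in sample
$j$ is

$$p_{ej} = d_{ej} - b_e,$$

giving an edges-by-samples matrix on which everything downstream runs:

1. **Feature selection** — edges that both discriminate tumors from
   normals (two-sided Wilcoxon rank-sum on perturbation values, ranked by
   |statistic|) and stay heterogeneous across tumors (SD over tumor
   samples); the top-6000 lists are intersected (both clamp to the edge
   count on smaller networks).
2. **Subtype discovery** — consensus clustering of tumor samples:
   1000 iterations, each subsampling 80% of samples, pairwise distance
   $1 - \rho_{\text{Spearman}}$ between sample columns, partitioning
   around medoids (PAM) for each $K$ in 2–10.  The consensus matrix entry
   is the co-clustering frequency among co-sampled iterations; final
   labels come from average-linkage hierarchical clustering of
   $1 - M_K$.  $K$ is chosen from the CDF of consensus values: with
   $A(K)$ the area under the CDF, the relative gain is
   $\Delta(2) = A(2)$ and $\Delta(K) = (A(K)-A(K-1))/A(K-1)$; the
   recommended $K$ is the largest one still gaining at least 0.1 — the
   elbow after which splitting adds only an insignificant increase.
3. **Propagation** — per discovered subtype, disjoint up-regulated
   signature gene sets (one-vs-rest Wilcoxon, BH-FDR < 0.05, mean log2
   difference > 0.2, capped at 200 genes, each gene assigned to its
   best subtype).  New samples are classified by **nearest-template
   prediction**: z-score the sample across the signature-gene union,
   take the cosine distance to each subtype's indicator template, assign
   the argmin, and attach a permutation p-value; samples with BH-FDR
   < 0.2 count as classified.
4. **Gene-set scoring** — single-sample GSEA: walking down each sample's
   expression ordering, in-set genes add their rank value raised to
   $\alpha = 0.25$ (normalized within the set) and out-of-set genes
   subtract uniformly; the score is the summed running-sum deviation.
5. **Marker screen** — candidate genes (the worst-prognosis subtype's
   signature) must reach ROC AUC > 0.9 for target-vs-rest in *every*
   cohort and univariate Cox p < 0.05 with HR > 1 in *every* cohort;
   survivors are ranked by mean Harrell's C-index across cohorts and the
   winner validated by a median-split Kaplan–Meier comparison and, where
   staining data exist, by H-scores (intensity 0–3 × percent stained,
   range 0–300).

# Key parameters

| parameter | default | units | why |
|---|---|---|---|
| edge confidence filter | > 0.8 | — | strict cut keeping only high-confidence interactions |
| feature top-k (diff / SD) | 6000 / 6000 | edges | conventional list sizes; clamp to the edge count on small networks |
| consensus iterations / subsample | 1000 / 0.8 | — | stable co-clustering frequencies; the synthetic demonstrations use 250 iterations, which already stabilizes the consensus at these sample sizes |
| K range | 2–10 | clusters | standard scan range |
| delta-area threshold | 0.1 | relative gain | formalizes the visual "insignificant increase" elbow |
| signature FDR / log2FC / cap | 0.05 / 0.2 / 200 | — | conventional one-vs-rest thresholds; 4 × 200 caps the signature union near 800 genes |
| NTP permutations / FDR | 1000 / 0.2 | — | classification confidence |
| ssGSEA exponent $\alpha$ | 0.25 | — | standard weighted-ECDF exponent; $\alpha = 0$ gives uniform increments |
| marker thresholds | AUC > 0.9, p < 0.05, HR > 1 | — | "consistency in all cohorts" read strictly: every threshold in every cohort |
| survival inclusion | time > 30 | days | excludes perioperative deaths |

# Design choices where the design was open

**Benchmark in rank space.**  The benchmark is the per-edge *average of
the normal samples' delta ranks*, not the delta rank of the average
expression profile.  The two differ; the rank-space average was chosen
because it keeps the whole statistic a pure function of within-sample
orderings, so the perturbation matrix is *exactly* invariant under any
strictly monotone per-sample transform (log, exp, quantile changes) —
the property that makes rank statistics portable across platforms.  When
normal orderings are fully conserved the two definitions coincide, and a
sample ordered like the conserved normal ordering has an exactly zero
perturbation column.

**Canonical edge orientation.**  Subtraction must run "in the same
direction" for every sample; no direction is privileged, so edges are
oriented lexicographically ($a < b$).  Flipping an edge negates its row
and nothing else of substance; clustering on a small instance is
verified to be unchanged.

**Ties.**  Average (fractional) ranks everywhere, making every statistic
symmetric in tied genes.  In ssGSEA, tied ranks are walked as one block
(running-sum deviations evaluated at block ends) so scores do not depend
on the arbitrary order within ties; an all-equal sample ties all set
scores exactly, and such ties are broken by subtype order and flagged
with margin 0.

**Differential edge statistic.**  The tumor-vs-normal "significant
difference" is measured by the Wilcoxon rank-sum statistic — rank-based,
matching the pipeline's philosophy and free of distributional
assumptions on perturbation values.

**PAM determinism.**  PAM uses the classic build+swap algorithm
(deterministic given the subsample); all subsampling flows from one
master seed, so consensus runs are bit-reproducible.

**NTP null distribution.**  A sample's prediction is the *minimum*
cosine distance over K templates, so the permutation null replicates
that selection: each draw generates K random same-size gene sets and
takes the minimum distance.  This keeps null p-values uniform (a
single-template null would be anti-conservative).  Ties in the argmin
are broken by subtype order and flagged.

**Cox ties.**  Efron tie handling (the common default); event times in
the synthetic data are continuous, so ties are rare.

# What the synthetic generator emulates — and what it does not

The generator plants exactly the structure the analysis assumes:

- a connected scale-free background network grown by preferential
  attachment (`attach_m` edges per new node from an initial set of
  `attach_m` unconnected nodes, giving $(n - m)\,m$ edges);
- normal samples as one baseline log2 profile plus i.i.d. Gaussian noise
  — conserved orderings up to noise;
- tumor subtypes that each own a disjoint subset (15%) of edges; in a
  subtype's samples one endpoint per owned edge is shifted **down** by
  `perturb_strength` log2 units ("flip-down"), flipping or displacing
  the edge's delta rank.  The shifted endpoint is the one least reused
  by other subtypes, and a gene carries shifts for at most two subtypes
  — subtype expression programs are kept largely gene-disjoint, as
  subtype biology is, which also keeps cross-subtype echo genes from
  masquerading as specific markers;
- one otherwise untouched gene planted as marker, shifted **up** by
  `marker_gene_effect` in the worst-prognosis subtype, making it the
  unique strongly subtype-specific up-regulated gene;
- exponential survival with subtype-specific hazards (default
  1 / 0.5 / 0.75 / 2, worst last; baseline median ~720 days), a 30-day
  offset so every record passes the inclusion filter, and independent
  censoring: with probability `censor_rate` a record is censored
  uniformly within its event time.

Reference study conditions (the defaults): 600 genes, ~1200 edges, 80
normal + 200 tumor samples, 4 subtypes, perturbation shift 3 log2 units
over noise SD 0.5.  Validation cohorts reuse the planted structure
(network, baseline, edge ownership, marker) with fresh samples, as
independent cohorts from one population would.

The generator deliberately does **not** emulate batch structure,
library-size or platform effects, correlated gene-gene noise,
tumor-adjacent "normal" contamination, or single-cell count noise.
Passing tests therefore show that the pipeline recovers planted
rank-level structure under clean conditions; they do not certify
performance against real-data confounders (normalization and batch
correction are out of scope by design — inputs are assumed
pre-normalized log-scale matrices).

# Numerical and degenerate-input conventions

- Constant sample columns make Spearman distance undefined and are
  rejected with an explicit error; sample pairs never co-sampled (too
  few iterations) are an error, not an NA.
- Genes missing from a cohort drop their edges cohort-wide (logged),
  never imputed; classification requires at least 50% signature coverage.
- Monotone Cox likelihoods (perfect separation) are flagged
  `converged = FALSE` rather than silently returned.
- All-censored groups give log-rank p = 1 with a warning; a C-index
  without comparable pairs is an error.
- Marker screens with impossible thresholds return an empty ranking,
  not an error; genes absent from any cohort fail with a reason.
- ssGSEA sets with no gene present score NA with a warning.

# Problem sizes used in the demonstrations

The test suite and the `analysis/` workflow run at the reference
conditions above with 250 consensus iterations (the full suite completes
in well under a minute; the end-to-end pipeline in seconds).  Unit tests
use much smaller instances with brute-force oracles: explicit
rank/delta/benchmark recomputation, exhaustive pair enumeration for AUC
and C-index, grid maximization of the Cox partial likelihood, hand
product-limit curves, and an explicit running-sum walk for ssGSEA.

# Known limitations

- The delta-area rule can be conservative when cluster separations are
  extremely clean at several K; the threshold is configurable.
- Signature derivation assumes each subtype has up-regulated genes; a
  subtype defined purely by losses with no relative gains anywhere would
  produce an empty signature (an explicit error).
- The permutation null shares random templates across samples for speed;
  p-values are marginally uniform but not independent across samples,
  which BH tolerates.
- H-score analysis starts from tabulated intensity/proportion records;
  no image analysis is attempted.
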