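---
title: "Signed connectome metrics and replicated model selection for crossover treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed connectome metrics and replicated model selection for crossover treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxynet)
```

## The analysis this package implements

`oxynet` implements a resting-state functional-connectivity analysis of
acute drug response in a two-visit, placebo-controlled crossover design.
Each subject contributes one ROI-by-time BOLD matrix per visit (one visit
on drug, one on placebo, order randomized in blocks within gender). The
pipeline is:

1. **ROI-level cleaning** — ordinary least-squares removal of three
   tissue-mean global signals and six rigid-body motion parameters, a
   0.009–0.08 Hz zero-phase band-pass, and temporal censoring: every
   corrupt time point is removed together with the volume before it and
   the two after it (windows unioned, clipped at the series ends).
2. **Connectome construction** — each cleaned series is standardized per
   node, its covariance is shrunk toward its own diagonal with the
   analytic optimal intensity, and the inverse is normalized into partial
   correlations: a signed, weighted, fully connected graph on all 294
   nodes. No thresholding or binarization is applied.
3. **Node metrics** — eigenvector centrality (EC, global influence: the
   absolute entries of the unit-norm principal eigenvector) and the signed
   weighted clustering coefficient (CC, local influence: signed triangle
   products over their maximal magnitude). Metrics always use the full
   graph; the 20 regions of interest are selected afterwards by row
   restriction, never recomputed on a subgraph.
4. **Treatment deltas and screening** — per (subject, node, metric)
   difference scores, placebo minus drug (positive = the drug reduced the
   measure), per-gender paired t-contrasts of the two conditions, and
   Welch/Spearman nuisance screens (scanner, smoking, head motion,
   subjective ratings), each family controlled by Benjamini–Hochberg FDR
   at 5%.
5. **Replicated best-subsets selection** — for each of eight models (two
   outcomes: childhood-trauma total and years of use; two genders; two
   metrics), ten replications of: a 70/30 train/holdout partition,
   exhaustive enumeration of predictor subsets (20 node deltas plus head
   motion, subsets up to size 5) fit on the training part and scored by
   held-out average squared error, then leave-one-out importance of the
   winning subset. Importances (each replication sums to 1) are
   accumulated; predictors with cumulative importance above 1 form the
   final set, which is fit simultaneously and pruned wherever a variance
   inflation factor exceeds 4 by keeping the cluster member with the best
   solo fit.

Because no imaging data accompany the design, the package ships a
first-class synthetic cohort generator that plants known structure at the
*covariance* level, so every stage above — not just the last — is
exercised by the recovery tests.

## The synthetic cohort

`simulate_cohort()` draws 39 female and 54 male subjects by default.
Covariates come from truncated normals matched to the cohort the design
emulates (e.g. childhood-trauma totals 51.2 (21.4) for women, 43.8 (14.3)
for men, clipped to the instrument's range 25–125 and decomposed into 25
items on a 1–5 scale; years of use 14.1 (7.7) / 18.3 (8.2)). Treatment
order is block-randomized within gender with block sizes 2 or 4. Corrupt
time points are i.i.d. at rate 0.12 (female) / 0.13 (male); series are 180
volumes at TR 2 s.

The population correlation matrix is block-structured: the four ROI region
classes (ACC, insula, amygdala, striatum) are intact communities at
within-community correlation 0.30, the remaining 274 nodes fill ten
communities whose strengths span 0.175–0.425, and a weak global factor
(0.08) couples everything. The heterogeneous strengths matter: identical
equicorrelated blocks make the principal eigenvalue degenerate and EC
ill-defined.

A treatment effect is planted as an additive perturbation (default 0.22)
on the target node's within-community correlations, applied only in the
specified gender and condition and scaled by a subject-specific response
multiplier (truncated normal, mean 1, SD 0.3) — the between-subject
heterogeneity that outcome links need. The default pattern: drug-induced
connectivity increases at right ACC and left dorsal amygdala in males, and
at right accumbens and right dorsal ACC in females. The magnitude was
calibrated once by forward simulation so the planted effects sit in the
regime the paired-contrast stage is designed to detect; at the defaults
all four planted cells are flagged by the CC contrasts. Flagged cells
beyond the four planted ones are not false positives in the usual sense:
the covariance perturbation genuinely alters the metrics of the target
node's community partners, and those spillover effects are sometimes
detected too.

Outcome links are planted through `plant_outcome()`: the linked outcome is
regenerated as `slope x z(true node delta) + noise` within the gender
group, where the *true* delta comes from the population partial-correlation
matrices of the two conditions (`true_node_deltas()`), and the default
slope gives a ground-truth R² of 0.30 per link.

### What the generator does not emulate

Signals are stationary Gaussian: no hemodynamics, no autocorrelation
beyond what the band-pass induces, no voxel level, no non-Gaussian
artifacts. Motion is a bounded random walk rescaled to a subject-level
mean framewise displacement (backward differences of the six parameters,
rotations converted on a 50 mm sphere) and contaminates the signal only
through small linear loadings, which is exactly the structure the nuisance
regression removes. Passing recovery tests therefore demonstrate the
statistical machinery, not robustness to the full mess of real fMRI.

## Numerical and design choices

**Shrinkage intensity.** The analytic diagonal-target intensity is the
ratio of the summed variance estimates of the off-diagonal correlations to
their summed squares, clipped to [0, 1] — the standard closed-form
estimator for shrinking correlations toward zero. With 294 nodes and only
~70–140 retained volumes the sample covariance is singular, so a positive
intensity is structurally required; at the defaults it comes out around
0.2. A manual override (`lambda`) exists, and per-node standardization
before estimation (default on) makes covariance and correlation coincide.

**Principal eigenvalue on a signed graph.** "Principal" is read as largest
|eigenvalue| of the signed matrix itself, with the absolute value applied
to the resulting unit-norm eigenvector. When +λ and −λ tie in magnitude
the positive one is taken; genuine multiplicities are resolved
deterministically (lexicographically largest |eigenvector|) with a
warning. A sensitivity mode computes EC on |M| instead.

**Clustering coefficient.** `CC_i = Σ w_ij w_iq w_jq / Σ |w_ij w_iq|` over
ordered pairs of distinct neighbors; the denominator bounds the numerator,
so CC ∈ [−1, 1], reducing to the usual triangle fraction in the binary
limit. Nodes with fewer than two incident edges get 0.

**Censoring order.** The band-pass requires a contiguous sampling grid, so
the order is regress → filter → censor, and the applied order is recorded
in the run manifest.

**Replication scheme (a deliberate deviation).** The commercial tool the
procedure emulates describes replicates as "a random sample with
replacement". We measured the null behavior of that scheme: with a
bootstrap resample, duplicated subjects land on both sides of the
subsequent 70/30 split, the holdout stops preventing overfitting, and the
fraction of pure-noise replications reported significant reaches 0.4–0.9
depending on where the final model is refit. Re-partitioning the cohort
afresh each replication and reporting the selected subset's fit on the
*training* partition (selection being driven by the independent holdout)
brings the null significance rate to ~0.05, i.e. the nominal level. The
defaults are therefore `resample = "partition"` and `refit = "train"`;
the leaky variants remain available (`"bootstrap"`, `"full"`) for
comparison. Outlier trimming (median ± 3 × 1.4826 MAD on the outcome, with
an off switch) is applied per replication; automatic variable
transformation is deliberately not reimplemented.

**Best-subsets enumeration.** Exhaustive enumeration up to size 5 of 21
candidates (27,895 subsets) per replication, scored from precomputed Gram
matrices in compiled code; ties in held-out ASE resolve to the
lexicographically first (hence smallest) subset, and singular subsets are
skipped. Small-p behavior is pinned to an all-subsets `lm` oracle in the
tests.

## What end-to-end recovery does and does not show

Three findings from the full-scale synthetic runs are worth knowing
before interpreting output.

*EC is insensitive to local planted effects.* A perturbation of one node's
community correlations moves the unit-norm principal eigenvector of a
294-node graph by very little, and between-subject estimation noise at
~100 retained volumes swamps it. The planted effects are recovered through
CC, not EC — consistent with CC being the locally sensitive measure.

*End-to-end outcome-link recovery is borderline by construction.* The
measured difference scores correlate with the true planted deltas at only
about 0.5–0.6 (estimation noise), so a planted link of ground-truth
R² = 0.30 arrives at the selection stage with an effective R² near 0.1 —
at n = 39–54 per gender that is at the edge of what replicated
best-subsets can single out of 21 candidates, and whether a given run
recovers a link depends on the seed. The delta-level recovery tests
(which run the planted link at its nominal R², bypassing estimation
noise) are where the selection machinery's correctness is established;
the end-to-end numbers in the acceptance output document the attenuated
regime honestly.

*Finite-sample CC deltas can flip sign relative to the asymptotic truth.*
In the population matrices, strengthening a node's edges *lowers* its
signed CC — the stronger hub edges explain away its neighbors' mutual
partial correlations. At T ≈ 110 retained volumes the estimated CC moves
the *opposite* way (estimation bias dominates; at T = 20,000 the sample
agrees with the population sign). `true_node_deltas()` deliberately
reports the asymptotic quantity; planted outcome links remain recoverable
because the selection stage is sign-agnostic, but the sign of a recovered
coefficient should not be read as the sign of the asymptotic effect.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on reduced cohorts (10–24 subjects, 28 nodes,
40–120 volumes) chosen so the suite exercises every code path at
interactive speed; the calibration and recovery checks use the full
n = 93, 21-predictor selection geometry over 50 and 10 seeds respectively.
The acceptance script runs one full-scale default pipeline (93 subjects,
294 nodes, 180 volumes) plus the same calibration loops.

## Known limitations

- The repeated-measures mixed model of the original analysis chain is
  replaced by per-node paired contrasts with FDR; interactions are probed
  through planted-effect recovery and the selection stage instead.
- Non-ROI node coordinates in the packaged parcellation are synthetic
  placeholders (the labels and counts are what the pipeline consumes).
- The generator's corrupt-point process is i.i.d.; real motion artifacts
  cluster in time, which would make censoring less costly than the ~0.42
  scrub fraction seen at the defaults.
- With ~70 retained volumes in the worst series, shrinkage keeps the
  estimate well-conditioned but partial correlations are heavily
  attenuated (99% of |weights| below ~0.06); analyses should be read as
  rank/contrast statements, not as edge-weight estimates.
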