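# oxynet

Graph-theory analysis of acute treatment response in resting-state
functional connectomes, for two-visit placebo-controlled crossover studies.
The motivating application is intranasal oxytocin in cocaine use disorder:
does a single dose reorganize the connectivity of stress- and
addiction-related nodes (ACC, insula, amygdala, striatum), and are those
node-level changes associated with childhood trauma severity and years of
drug use, separately in men and women?

The package implements the full chain, and ships a synthetic cohort
generator with planted ground truth so the chain is testable end to end
without any imaging data.

## The statistics at the core

For each subject-visit ROI series (294 nodes, ~6 min at TR = 2 s), after
nuisance regression, 0.009–0.08 Hz band-pass and motion censoring
(each corrupt volume plus one before and two after), the connectome is the
signed weighted partial-correlation graph

  W_ij = −P_ij / √(P_ii P_jj),  P = Σ̂⁻¹,  Σ̂ = (1−λ) S + λ diag(S),

with λ the analytic optimal shrinkage intensity toward the diagonal target
(mandatory here, since T ≪ N makes S singular). Two node measures are
computed on the full graph:

- eigenvector centrality (global influence): `C_Eig[i] = |x_i|` for the
  unit-norm eigenvector x of the principal (largest-|λ′|) eigenvalue of W;
- signed weighted clustering coefficient (local influence):
  `CC_i = Σ_{j≠q} w_ij w_iq w_jq / Σ_{j≠q} |w_ij w_iq|` ∈ [−1, 1].

Treatment response is the placebo-minus-drug difference score per
(subject, node, metric); positive means the drug reduced the measure.
Screening uses per-gender paired t-contrasts and Welch/Spearman nuisance
checks, each family under Benjamini–Hochberg FDR at 5%. The association
stage runs, for each of 8 models (outcome CTQ/years-of-use × gender ×
metric), 10 replications of best-subsets regression — 70/30
train/holdout partition, exhaustive subsets of the 20 node deltas plus
head motion scored by held-out average squared error — accumulates
leave-one-out predictor importance across replications, keeps predictors
with cumulative importance > 1, and prunes any final-model VIF > 4.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic cohort and write tables under `results/analysis/`:

```sh
OXYNET_SEED=1 Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_connectome.R
Rscript analysis/04_metrics.R
Rscript analysis/05_screen.R
OXYNET_SEED=1 Rscript analysis/06_model_selection.R
```

Output from the run above (seed 1):

```
Simulating cohort: 39 female + 54 male, 180 volumes at TR 2 s
  female: n=39, CTQ 57.8 (17.7), years of use 15.3 (7.1)
  male: n=54, CTQ 43.5 (9.9), years of use 19.2 (6.7)
  planted outcome links (true R2): CTQ_female 0.3, YRSUSE_male 0.3, YRSUSE_female 0.3
...
  mean scrub fraction (female): 0.413
  mean scrub fraction (male): 0.424
  shrinkage intensity lambda: mean 0.236, range 0.154-0.302
...
Paired contrasts: 4 of 80 (node, metric, gender) cells flagged at FDR 0.05
  female r_dacc/cc: mean delta -0.0004 (p=2.1e-06) -> connectivity increased on drug
  female r_nacc/cc: mean delta -0.00027 (p=0.00027) -> connectivity increased on drug
  male r_acc/cc: mean delta -0.00039 (p=1.2e-08) -> connectivity increased on drug
  male l_damg/cc: mean delta -0.00046 (p=7.2e-10) -> connectivity increased on drug
Covariate screens: 0 of 1040 flagged
...
Planted link recovery:
  CTQ_female_ec: planted node r_dacc, top-importance node r_racc (not recovered)
  YRSUSE_male_cc: planted node l_damg, top-importance node l_damg (recovered)
  YRSUSE_female_cc: planted node r_nacc, top-importance node r_dacc (not recovered)
```

Reading this: the four planted gender-specific drug effects are exactly
the four flagged contrast cells (negative delta = connectivity increased
on drug), no nuisance covariate survives FDR, and the male years-of-use
link is recovered by model selection with the planted amygdala node as the
top cumulative-importance predictor (5/10 significant replications, mean
accuracy 18%). End-to-end link recovery is borderline by construction —
estimation noise attenuates the planted R² = 0.3 to roughly 0.1 at the
selection stage, so which links are recovered varies with the seed; the
vignette quantifies the attenuation and explains why the
centrality-based links are the hardest.

The same pipeline is available programmatically:

```r
library(oxynet)
run <- run_pipeline(default_config(), seed = 1, outdir = "results/run1")
subset(run$contrasts, q_flag)
run$sweep$comparison
```

## Layout

- `R/`, `src/` — the package: generator, preprocessing, connectome,
  metrics, screening, model selection, pipeline orchestration.
- `analysis/` — the numbered study drivers shown above.
- `inst/extdata/` — packaged node tables (20 real ROI coordinates; the
  other 274 coordinates are synthetic placeholders, see the vignette).
- `vignettes/connectome-treatment-response.Rmd` — the methods vignette:
  model, assumptions, calibration choices, known limitations.
- `tests/testthat/` — unit, property and acceptance tests.
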