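#!/usr/bin/env Rscript
# Stage 2 — ROI-level cleaning.
# Nuisance regression (intercept + 3 tissue means + 6 motion parameters),
# 0.009-0.08 Hz zero-phase band-pass, then censoring of each corrupt time
# point with its preceding and two following volumes.

suppressPackageStartupMessages(library(oxynet))
outdir <- "results/analysis"
cohort <- readRDS(file.path(outdir, "cohort.rds"))
cfg <- readRDS(file.path(outdir, "config.rds"))

message("Cleaning ", length(cohort$series), " subject-visit series")
clean <- lapply(cohort$series, preprocess_series, config = cfg)

scrub <- data.frame(
  series = names(clean),
  subject_id = vapply(clean, `[[`, "", "subject_id"),
  condition = vapply(clean, `[[`, "", "condition"),
  scrub_fraction = vapply(clean, `[[`, 1, "scrub_fraction"),
  n_retained = vapply(clean, function(x) length(x$retained_index), 1L),
  row.names = NULL)
gmap <- setNames(cohort$subjects$gender, cohort$subjects$subject_id)
for (g in c("female", "male"))
  message(sprintf("  mean scrub fraction (%s): %.3f", g,
                  mean(scrub$scrub_fraction[gmap[scrub$subject_id] == g])))
message(sprintf("  retained volumes: %d-%d of %d",
                min(scrub$n_retained), max(scrub$n_retained), cfg$n_time))

write.csv(scrub, file.path(outdir, "scrub_summary.csv"), row.names = FALSE)
saveRDS(clean, file.path(outdir, "clean.rds"))
message("Stage 2 done")
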