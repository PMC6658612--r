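#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end under one master seed: cohort
#' simulation, ROI-level cleaning (nuisance regression, band-pass,
#' censoring), shrinkage partial-correlation connectomes, node metrics
#' (eigenvector centrality, signed clustering coefficient), placebo-minus-
#' drug difference scores, per-gender paired condition contrasts and
#' covariate screens with FDR control, and the eight-model replicated
#' best-subsets sweep (outcome x gender x metric). A run manifest records
#' the seed, configuration checksum, stage order, per-stage row counts and
#' the shrinkage intensities actually used.
#'
#' @param config Pipeline configuration, see [default_config()].
#' @param seed Master seed.
#' @param outdir Optional directory; when given, stage outputs are written
#'   as plain-text tables (see [write_pipeline_outputs()]).
#' @param write_matrices Also write every subject-visit connectivity matrix
#'   as TSV (large; off by default).
#' @param verbose Print stage progress.
#' @return A list of class `oxynet_run` with elements `cohort`, `clean`,
#'   `connectomes`, `metric_table`, `deltas`, `contrasts`, `screens`,
#'   `sweep`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1, outdir = NULL,
                         write_matrices = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  say("simulating cohort (", config$n_female, " female + ", config$n_male,
      " male, ", config$n_time, " volumes)")
  cohort <- simulate_cohort(config, seed = seed)

  say("preprocessing ", length(cohort$series), " subject-visit series")
  clean <- lapply(cohort$series, preprocess_series, config = config)

  say("building connectomes")
  connectomes <- lapply(clean, build_connectome, config = config)
  lambdas <- vapply(connectomes, attr, numeric(1), which = "lambda")

  say("computing node metrics")
  metric_table <- compute_metric_table(connectomes, cohort$subjects,
                                       ec_mode = config$ec_mode)

  roi_nodes <- config$roi$node_id
  deltas <- compute_deltas(metric_table, roi_nodes = roi_nodes)

  say("screening")
  contrasts <- do.call(rbind, lapply(c("female", "male"), function(g)
    paired_condition_contrast(metric_table, cohort$subjects, g,
                              roi_nodes = roi_nodes, q = config$fdr_q)))
  roi_metrics <- metric_table[metric_table$node_id %in% roi_nodes, ]
  screens <- covariate_screens(deltas, roi_metrics, cohort$subjects,
                               q = config$fdr_q)

  say("running the eight-model selection sweep")
  sweep <- run_model_sweep(deltas, cohort$subjects, config,
                           seed = seed + 1L)

  scrub <- vapply(clean, function(x) x$scrub_fraction, numeric(1))
  manifest <- list(
    seed = seed,
    config_checksum = config_checksum(config),
    package_version = as.character(utils::packageVersion("oxynet")),
    stage_order = c("simulate", "regress", "bandpass", "censor",
                    "connectome", "metrics", "delta", "screen", "select"),
    n_subjects = nrow(cohort$subjects),
    n_series = length(cohort$series),
    n_nodes = nrow(config$nodes),
    n_roi = length(roi_nodes),
    scrub_fraction = c(mean = mean(scrub), min = min(scrub),
                       max = max(scrub)),
    lambda = c(mean = mean(lambdas), min = min(lambdas),
               max = max(lambdas)),
    rows = c(metric_table = nrow(metric_table), deltas = nrow(deltas),
             contrasts = nrow(contrasts), screens = nrow(screens)),
    n_models = length(sweep$models))

  run <- structure(list(cohort = cohort, clean = clean,
                        connectomes = connectomes,
                        metric_table = metric_table, deltas = deltas,
                        contrasts = contrasts, screens = screens,
                        sweep = sweep, manifest = manifest),
                   class = "oxynet_run")
  if (!is.null(outdir))
    write_pipeline_outputs(run, outdir, write_matrices = write_matrices)
  run
}

# order-insensitive-to-nothing checksum of the configuration (plain lists
# and data frames only); recorded in the manifest for reproducibility checks
config_checksum <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  v <- as.integer(raw)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Write pipeline outputs as plain-text tables
#'
#' Writes the subject table (CTQ items expanded to one column per item),
#' per-series scrub sidecars, the long node-metric table, the delta table,
#' the screening reports, per-replication and cumulative-importance tables
#' for each of the eight models, the final-model report and the JSON run
#' manifest.
#'
#' @param run An `oxynet_run` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param write_matrices Also write each subject-visit connectivity matrix
#'   as a node x node TSV with id header row/column.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(run, outdir, write_matrices = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  subj <- run$cohort$subjects
  items <- do.call(rbind, subj$ctq_items)
  colnames(items) <- sprintf("ctq_item_%02d", 1:25)
  write.csv(cbind(subj[setdiff(names(subj), "ctq_items")], items),
            file.path(outdir, "subjects.csv"), row.names = FALSE)

  sidecar <- data.frame(
    series = names(run$clean),
    subject_id = vapply(run$clean, `[[`, "", "subject_id"),
    visit = vapply(run$clean, `[[`, 1L, "visit"),
    condition = vapply(run$clean, `[[`, "", "condition"),
    scrub_fraction = vapply(run$clean, `[[`, 1, "scrub_fraction"),
    n_retained = vapply(run$clean, function(x) length(x$retained_index), 1L),
    row.names = NULL)
  write.csv(sidecar, file.path(outdir, "scrub_summary.csv"),
            row.names = FALSE)

  write.csv(run$metric_table, file.path(outdir, "node_metrics.csv"),
            row.names = FALSE)
  write.csv(run$deltas, file.path(outdir, "treatment_deltas.csv"),
            row.names = FALSE)
  write.csv(run$contrasts, file.path(outdir, "paired_contrasts.csv"),
            row.names = FALSE)
  write.csv(run$screens, file.path(outdir, "covariate_screens.csv"),
            row.names = FALSE)

  reps <- do.call(rbind, lapply(names(run$sweep$models), function(nm) {
    s <- run$sweep$models[[nm]]
    do.call(rbind, lapply(s$replications, function(r) data.frame(
      model = nm, replication = r$replication_id,
      subset = paste(r$selected_subset, collapse = "+"),
      test_ase = r$test_ase, adjusted_r2 = r$adjusted_r2,
      model_p = r$model_p, aic = r$aic, stringsAsFactors = FALSE)))
  }))
  write.csv(reps, file.path(outdir, "replications.csv"), row.names = FALSE)

  cum <- do.call(rbind, lapply(names(run$sweep$models), function(nm) {
    s <- run$sweep$models[[nm]]
    data.frame(model = nm, predictor = names(s$cumulative_importance),
               cumulative_importance = unname(s$cumulative_importance),
               final = names(s$cumulative_importance) %in%
                 s$final_predictors, stringsAsFactors = FALSE)
  }))
  write.csv(cum, file.path(outdir, "cumulative_importance.csv"),
            row.names = FALSE)

  finals <- do.call(rbind, lapply(names(run$sweep$models), function(nm) {
    s <- run$sweep$models[[nm]]
    if (is.null(s$final_model)) return(data.frame(
      model = nm, predictor = NA, coefficient = NA, vif = NA,
      adjusted_r2 = NA, model_p = NA, stringsAsFactors = FALSE))
    fm <- s$final_model
    data.frame(model = nm,
               predictor = names(coef(fm$fit)),
               coefficient = unname(coef(fm$fit)),
               vif = unname(c(NA, fm$vif[names(coef(fm$fit))[-1]])),
               adjusted_r2 = fm$adjusted_r2, model_p = fm$model_p,
               stringsAsFactors = FALSE)
  }))
  write.csv(finals, file.path(outdir, "final_models.csv"),
            row.names = FALSE)
  write.csv(run$sweep$comparison, file.path(outdir, "metric_comparison.csv"),
            row.names = FALSE)

  if (write_matrices) {
    mdir <- file.path(outdir, "connectomes")
    dir.create(mdir, showWarnings = FALSE)
    for (nm in names(run$connectomes)) {
      m <- run$connectomes[[nm]]
      write.table(data.frame(node_id = rownames(m), m, check.names = FALSE),
                  file.path(mdir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- run$manifest
  if (!is.null(run$cohort$truth$planted_r2))
    manifest$planted_r2 <- as.list(run$cohort$truth$planted_r2)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Write a simulated cohort as delimited text
#'
#' Subject table as CSV plus, per subject-visit, a node x time signal TSV
#' (nodes as rows, a header row of time indices) with companion corrupt-mask
#' and motion-parameter TSVs, and a ground-truth manifest (JSON) recording
#' the effect specification and seed.
#'
#' @param cohort An `oxynet_cohort` from [simulate_cohort()].
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  subj <- cohort$subjects
  items <- do.call(rbind, subj$ctq_items)
  colnames(items) <- sprintf("ctq_item_%02d", 1:25)
  write.csv(cbind(subj[setdiff(names(subj), "ctq_items")], items),
            file.path(outdir, "subjects.csv"), row.names = FALSE)
  sdir <- file.path(outdir, "series")
  dir.create(sdir, showWarnings = FALSE)
  for (nm in names(cohort$series)) {
    s <- cohort$series[[nm]]
    sig <- s$signal
    colnames(sig) <- seq_len(ncol(sig))
    write.table(data.frame(node_id = rownames(sig), sig,
                           check.names = FALSE),
                file.path(sdir, paste0(nm, "_signal.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(t = seq_along(s$corrupt_mask),
                           corrupt = as.integer(s$corrupt_mask)),
                file.path(sdir, paste0(nm, "_mask.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- s$motion_params
    write.table(data.frame(param = rownames(mp), mp, check.names = FALSE),
                file.path(sdir, paste0(nm, "_motion.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- list(seed = cohort$seed,
                treatment_effects = cohort$truth$treatment_effects,
                outcome_links = cohort$truth$outcome_links,
                noise_sd = cohort$truth$noise_sd,
                planted_r2 = as.list(cohort$truth$planted_r2))
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.oxynet_run <- function(x, ...) {
  m <- x$manifest
  cat("oxynet pipeline run (seed ", m$seed, ")\n", sep = "")
  cat("  subjects: ", m$n_subjects, ", series: ", m$n_series,
      ", nodes: ", m$n_nodes, " (", m$n_roi, " ROIs)\n", sep = "")
  cat(sprintf("  mean scrub fraction: %.3f, mean shrinkage lambda: %.3f\n",
              m$scrub_fraction["mean"], m$lambda["mean"]))
  cat("  flagged contrasts:",
      paste(with(x$contrasts[x$contrasts$q_flag, ],
                 paste0(node_id, "/", metric, " (", gender, ")")),
            collapse = ", "), "\n")
  cat("  model comparison:\n")
  print(x$sweep$comparison, row.names = FALSE)
  invisible(x)
}
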