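#' Default planted-effect specification
#'
#' Encodes the ground truth the synthetic cohort carries: gender-specific
#' drug-condition connectivity effects on designated nodes, and linear links
#' between node-level treatment-difference scores and the two clinical
#' outcomes (childhood-trauma total, years of use). The default pattern
#' mirrors the structure the analyses are designed to detect: drug-induced
#' connectivity increases in ACC/amygdala nodes for males and ACC/accumbens
#' nodes for females, an ACC centrality link to childhood trauma in females,
#' and ACC-linked years-of-use associations in both genders.
#'
#' @param treatment_magnitude Additive perturbation applied to the target
#'   node's within-community correlations under the active condition
#'   (dimensionless correlation units).
#' @param link_r2 Target proportion of outcome variance explained by each
#'   planted delta link (per link, before estimation noise).
#' @param noise_sd Standard deviation of the Gaussian outcome noise on the
#'   standardized scale.
#' @return A list with elements `treatment_effects` (data.frame: `node_id`,
#'   `gender`, `condition`, `magnitude`), `outcome_links` (data.frame:
#'   `outcome`, `gender`, `node_id`, `metric`, `slope`) and `noise_sd`.
#' @export
default_effects <- function(treatment_magnitude = 0.22, link_r2 = 0.3,
                            noise_sd = 1) {
  stopifnot(link_r2 > 0, link_r2 < 1, noise_sd > 0)
  # slope on a standardized predictor giving var(signal)/var(total) = link_r2
  slope <- sqrt(link_r2 / (1 - link_r2)) * noise_sd
  list(
    treatment_effects = data.frame(
      node_id = c("r_acc", "l_damg", "r_nacc", "r_dacc"),
      gender = c("male", "male", "female", "female"),
      condition = "OXY",
      magnitude = treatment_magnitude,
      stringsAsFactors = FALSE
    ),
    outcome_links = data.frame(
      outcome = c("CTQ", "YRSUSE", "YRSUSE"),
      gender = c("female", "male", "female"),
      node_id = c("r_dacc", "l_damg", "r_nacc"),
      metric = c("ec", "cc", "cc"),
      slope = slope,
      stringsAsFactors = FALSE
    ),
    noise_sd = noise_sd
  )
}

#' Default pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one list. Numeric
#' defaults follow the study design they emulate: a 39-female / 54-male
#' two-visit crossover, 6-minute runs at TR 2 s (180 volumes), corrupt
#' time-point rates of 0.12 (female) / 0.13 (male), a 0.009-0.08 Hz pass
#' band, censoring windows of one preceding and two following time points,
#' a 70/30 train/holdout split, 10 selection replications, cumulative
#' importance threshold 1, VIF threshold 4 and FDR level 0.05.
#'
#' @param n_female,n_male Group sizes.
#' @param n_time Volumes per run.
#' @param tr_seconds Repetition time in seconds.
#' @param corrupt_rate Named vector of per-gender corrupt time-point rates.
#' @param effects Planted ground truth, see [default_effects()].
#' @param nodes,roi Node tables, see [parcellation_table()] and [roi_table()].
#' @param ... Overrides for any other configuration entry.
#' @return A named list of class `oxynet_config`.
#' @export
default_config <- function(n_female = 39, n_male = 54, n_time = 180,
                           tr_seconds = 2,
                           corrupt_rate = c(female = 0.12, male = 0.13),
                           effects = default_effects(),
                           nodes = parcellation_table(),
                           roi = roi_table(), ...) {
  cfg <- list(
    n_female = n_female, n_male = n_male,
    n_time = n_time, tr_seconds = tr_seconds,
    corrupt_rate = corrupt_rate,
    # generator structure
    n_blocks = 14, base_within_r = 0.3,
    response_sd = 0.3, artifact_sd = 0.1,
    head_motion_mean = 0.15, head_motion_sd = 0.06, head_motion_min = 0.02,
    # preprocessing
    band_low = 0.009, band_high = 0.08,
    censor_pre = 1, censor_post = 2,
    # connectome
    lambda = NULL, standardize = TRUE,
    # metrics
    ec_mode = "signed",
    # screening / selection
    fdr_q = 0.05,
    split_fraction = 0.7, n_replications = 10, max_subset_size = 5,
    importance_threshold = 1.0, vif_threshold = 4.0,
    trim = TRUE, trim_k = 3,
    resample = "partition", refit = "train",
    # planted truth and node tables
    effects = effects, nodes = nodes, roi = roi,
    # cohort covariate targets: mean/sd by gender
    covariates = list(
      age = list(female = c(40.0, 8.5), male = c(44.5, 9.8), lo = 18, hi = 70),
      years_use = list(female = c(14.1, 7.7), male = c(18.3, 8.2),
                       lo = 0.5, hi = 45),
      ctq_total = list(female = c(51.2, 21.4), male = c(43.8, 14.3),
                       lo = 25, hi = 125),
      smoker_prop = c(female = 0.846, male = 0.759),
      prisma_n = c(female = 3, male = 1),
      ratings = list(
        craving = list(v1 = list(female = c(2.3, 2.7), male = c(2.7, 2.5)),
                       v2 = list(female = c(2.2, 2.5), male = c(2.5, 2.5)),
                       lo = 0, hi = 10),
        anxiety = list(v1 = list(female = c(2.4, 2.4), male = c(2.3, 2.2)),
                       v2 = list(female = c(2.0, 2.4), male = c(2.1, 2.5)),
                       lo = 0, hi = 10),
        stress = list(v1 = list(female = c(1.5, 2.3), male = c(2.2, 2.4)),
                      v2 = list(female = c(1.5, 2.4), male = c(1.7, 2.2)),
                      lo = 0, hi = 10),
        stai = list(v1 = list(female = c(32.2, 9.7), male = c(35.2, 12.1)),
                    v2 = list(female = c(32.4, 12.0), male = c(34.4, 12.0)),
                    lo = 20, hi = 80),
        ccq = list(v1 = list(female = c(5.5, 1.3), male = c(5.5, 1.1)),
                   v2 = list(female = c(5.7, 1.3), male = c(5.6, 1.2)),
                   lo = 1, hi = 10)
      )
    )
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "oxynet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_female < 0 || cfg$n_male < 0 || cfg$n_female + cfg$n_male < 1)
    stop("group sizes must be nonnegative and sum to at least 1")
  if (cfg$n_time < 8) stop("series length must be at least 8 volumes")
  if (cfg$tr_seconds <= 0) stop("tr_seconds must be positive")
  if (any(cfg$corrupt_rate < 0) || any(cfg$corrupt_rate >= 1))
    stop("corrupt_rate must lie in [0, 1)")
  nyq <- 1 / (2 * cfg$tr_seconds)
  if (!(cfg$band_low > 0 && cfg$band_low < cfg$band_high &&
        cfg$band_high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (",
         signif(nyq, 3), " Hz)")
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)")
  if (cfg$n_replications < 1) stop("n_replications must be at least 1")
  if (!cfg$resample %in% c("partition", "bootstrap"))
    stop("resample must be 'partition' or 'bootstrap'")
  if (!cfg$refit %in% c("train", "full"))
    stop("refit must be 'train' or 'full'")
  te <- cfg$effects$treatment_effects
  ol <- cfg$effects$outcome_links
  bad <- setdiff(c(te$node_id, ol$node_id), cfg$nodes$node_id)
  if (length(bad))
    stop("effect specification references unknown nodes: ",
         paste(bad, collapse = ", "))
  invisible(cfg)
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}
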