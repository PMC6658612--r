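#' Block-structured base correlation for the synthetic cohort
#'
#' Deterministically assigns every node to one of `n_blocks` communities
#' (the four ROI region classes — ACC, insula, amygdala, striatum — are kept
#' as intact communities) and returns the population correlation matrix with
#' `base_within_r` inside communities and zero between them.
#'
#' @param config An `oxynet_config` list, see [default_config()].
#' @return An N x N correlation matrix with node-id dimnames and a `blocks`
#'   attribute (integer community labels).
#' @export
build_base_cov <- function(config = default_config()) {
  nodes <- config$nodes
  n <- nrow(nodes)
  blocks <- integer(n)
  region_block <- c(ACC = 1L, insula = 2L, amygdala = 3L, striatum = 4L)
  is_roi <- nodes$region_class %in% names(region_block)
  blocks[is_roi] <- region_block[nodes$region_class[is_roi]]
  nb <- max(config$n_blocks, 5L)
  # filler nodes round-robin over all communities after the ROI ones
  blocks[!is_roi] <- 5L + (seq_len(sum(!is_roi)) - 1L) %% (nb - 4L)
  # heterogeneous community strengths around base_within_r plus a weak
  # global factor: breaks the eigenvalue degeneracy of identical
  # equicorrelated blocks and keeps the graph connected
  g <- 0.08
  spread <- 0.25
  r_block <- numeric(nb)
  r_block[1:4] <- config$base_within_r     # ROI communities at nominal strength
  r_block[5:nb] <- config$base_within_r - spread / 2 +
    spread * (seq_len(nb - 4) - 1) / (nb - 5)
  r_block <- pmin(pmax(r_block, g + 0.02), 0.95)
  cc <- matrix(g, n, n)
  same <- outer(blocks, blocks, "==")
  cc[same] <- r_block[blocks[row(cc)[same]]]
  diag(cc) <- 1
  dimnames(cc) <- list(nodes$node_id, nodes$node_id)
  attr(cc, "blocks") <- setNames(blocks, nodes$node_id)
  cc
}

# apply the treatment-effect rows relevant to (gender, condition) to the base
# correlation: each effect adds magnitude * mult to the target node's
# correlations with its own community, then positive-definiteness is enforced
# by halving the perturbation if needed.
condition_cov <- function(base_cov, effects, gender, condition, mult = 1) {
  te <- effects$treatment_effects
  te <- te[te$gender == gender & te$condition == condition, , drop = FALSE]
  if (!nrow(te)) return(base_cov)
  blocks <- attr(base_cov, "blocks")
  scale <- 1
  for (try in 1:20) {
    m <- base_cov
    for (k in seq_len(nrow(te))) {
      v <- te$node_id[k]
      partners <- names(blocks)[blocks == blocks[v]]
      partners <- setdiff(partners, v)
      add <- te$magnitude[k] * mult * scale
      m[v, partners] <- pmin(pmax(m[v, partners] + add, -0.9), 0.9)
      m[partners, v] <- m[v, partners]
    }
    ok <- !inherits(try(chol(m), silent = TRUE), "try-error")
    if (ok) {
      attr(m, "blocks") <- blocks
      return(m)
    }
    scale <- scale / 2
  }
  warning("could not keep perturbed covariance positive definite; ",
          "returning base covariance")
  base_cov
}

#' Simulate one subject-visit ROI time-series
#'
#' Draws a zero-mean stationary Gaussian node x time signal whose covariance
#' is the population base covariance modified by the treatment effects that
#' apply to this subject's gender and this visit's condition, plus small
#' loadings on three tissue-mean global signals and six head-motion
#' parameters (so that nuisance regression has real structure to remove).
#' A corrupt-time-point mask is drawn i.i.d. at the gender-specific rate and
#' the motion trace is a bounded random walk rescaled to the subject's
#' summary framewise displacement.
#'
#' @param subject One-row subject data.frame (as produced by
#'   [simulate_cohort()]).
#' @param visit Visit number, 1 or 2.
#' @param truth Planted-effect specification, see [default_effects()].
#' @param base_cov Population base covariance, see [build_base_cov()].
#' @param config Pipeline configuration.
#' @param seed Integer seed for this draw.
#' @return A list of class `roi_timeseries` with elements `subject_id`,
#'   `visit`, `condition`, `tr_seconds`, `signal` (node x time),
#'   `corrupt_mask`, `motion_params` (6 x time) and `global_signals`
#'   (3 x time).
#' @export
simulate_timeseries <- function(subject, visit, truth, base_cov,
                                config = default_config(), seed = NULL) {
  stopifnot(visit %in% c(1L, 2L))
  if (!is.null(seed)) set.seed(seed)
  if (!isSymmetric(unname(base_cov), tol = 1e-8) ||
      inherits(try(chol(base_cov), silent = TRUE), "try-error"))
    stop("base_cov must be a symmetric positive-definite matrix")
  bad <- setdiff(truth$treatment_effects$node_id, rownames(base_cov))
  if (length(bad))
    stop("treatment effects reference unknown nodes: ",
         paste(bad, collapse = ", "))

  condition <- if (visit == 1L) subject$visit1_condition else subject$visit2_condition
  n_time <- config$n_time
  covm <- condition_cov(base_cov, truth, subject$gender, condition,
                        mult = subject$response_mult)
  n <- nrow(covm)
  R <- chol(covm)
  signal <- crossprod(R, matrix(rnorm(n * n_time), n, n_time))
  rownames(signal) <- rownames(covm)

  # slow tissue-mean surrogates: unit-variance AR(1)
  gs <- t(sapply(1:3, function(i) {
    g <- as.numeric(stats::filter(rnorm(n_time), 0.9, method = "recursive"))
    as.numeric(scale(g))
  }))
  rownames(gs) <- c("gray", "white", "csf")

  # bounded random-walk motion trace rescaled to the subject's mean FD
  steps <- matrix(rnorm(6 * n_time, sd = rep(c(0.02, 0.0004), each = 3)),
                  6, n_time)
  fd <- framewise_displacement(steps, increments = TRUE)
  target <- subject$head_motion
  if (mean(fd) > 0) steps <- steps * target / mean(fd)
  walk <- t(apply(steps, 1, cumsum))
  bound <- rep(c(2, 0.04), each = 3)
  for (r in 1:6) {  # reflect into [-bound, bound]
    b <- bound[r]
    walk[r, ] <- abs(((walk[r, ] + b) %% (4 * b)) - 2 * b) - b
  }
  rownames(walk) <- c("tx", "ty", "tz", "rx", "ry", "rz")

  if (config$artifact_sd > 0) {
    zgs <- t(apply(gs, 1, function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x))
    zmp <- t(apply(walk, 1, function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x))
    signal <- signal +
      matrix(rnorm(n * 3, sd = config$artifact_sd), n, 3) %*% zgs +
      matrix(rnorm(n * 6, sd = config$artifact_sd), n, 6) %*% zmp
  }

  rate <- unname(config$corrupt_rate[subject$gender])
  mask <- runif(n_time) < rate

  structure(list(subject_id = subject$subject_id, visit = as.integer(visit),
                 condition = condition, tr_seconds = config$tr_seconds,
                 signal = signal, corrupt_mask = mask,
                 motion_params = walk, global_signals = gs),
            class = "roi_timeseries")
}

#' Mean framewise displacement of a motion trace
#'
#' Sum of absolute backward differences of the six rigid-body parameters,
#' with the three rotation parameters (rows 4-6, radians) converted to mm on
#' a 50 mm sphere.
#'
#' @param motion_params 6 x time matrix (translations mm, rotations rad).
#' @param increments If `TRUE`, `motion_params` already holds the backward
#'   differences.
#' @return Numeric vector of per-frame displacements (first frame 0 when
#'   differencing).
#' @export
framewise_displacement <- function(motion_params, increments = FALSE) {
  d <- if (increments) motion_params else
    cbind(0, t(apply(motion_params, 1, diff)))
  w <- rep(c(1, 50), each = 3)
  colSums(abs(d) * w)
}

# draws the subject covariate table; assumes RNG already seeded
simulate_subjects <- function(config) {
  cv <- config$covariates
  n <- config$n_female + config$n_male
  gender <- rep(c("female", "male"), c(config$n_female, config$n_male))
  draw <- function(spec) {
    out <- numeric(n)
    for (g in c("female", "male")) {
      i <- gender == g
      out[i] <- rtruncnorm(sum(i), spec[[g]][1], spec[[g]][2],
                           spec$lo, spec$hi)
    }
    out
  }
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    gender = gender,
    age_years = round(draw(cv$age), 1),
    years_use = round(draw(cv$years_use), 1),
    ctq_total = round(draw(cv$ctq_total)),
    stringsAsFactors = FALSE
  )
  subjects$ctq_items <- I(lapply(subjects$ctq_total, ctq_items_from_total))
  subjects$smoker <- runif(n) < unname(cv$smoker_prop[gender])
  subjects$scanner <- "TRIO"
  for (g in c("female", "male")) {
    k <- unname(cv$prisma_n[g])
    idx <- which(gender == g)
    if (k > 0 && length(idx))
      subjects$scanner[sample(idx, min(k, length(idx)))] <- "PRISMA"
  }
  subjects$treatment_order <- NA_character_
  for (g in c("female", "male")) {
    idx <- which(gender == g)
    subjects$treatment_order[idx] <- block_randomize(length(idx))
  }
  subjects$visit1_condition <- ifelse(subjects$treatment_order == "OXY_first",
                                      "OXY", "PBO")
  subjects$visit2_condition <- ifelse(subjects$treatment_order == "OXY_first",
                                      "PBO", "OXY")
  subjects$head_motion <- rtruncnorm(n, config$head_motion_mean,
                                     config$head_motion_sd,
                                     lo = config$head_motion_min)
  subjects$response_mult <- rtruncnorm(n, 1, config$response_sd, lo = 0)
  for (r in names(cv$ratings)) {
    spec <- cv$ratings[[r]]
    for (v in c("v1", "v2")) {
      out <- numeric(n)
      for (g in c("female", "male")) {
        i <- gender == g
        out[i] <- rtruncnorm(sum(i), spec[[v]][[g]][1], spec[[v]][[g]][2],
                             spec$lo, spec$hi)
      }
      subjects[[paste0(r, "_", v)]] <- round(out, 1)
    }
  }
  subjects
}

# balanced block randomization with block sizes drawn from {2, 4}
block_randomize <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    b <- sample(c(2L, 4L), 1)
    out <- c(out, sample(rep(c("OXY_first", "PBO_first"), b / 2)))
  }
  out[seq_len(n)]
}

# 25 items on a 1-5 scale summing to `total`; uniform over the capped slots
ctq_items_from_total <- function(total) {
  total <- min(max(round(total), 25), 125)
  extra <- total - 25
  items <- rep(1L, 25)
  if (extra > 0) {
    slots <- rep(seq_len(25), each = 4)
    items <- items + tabulate(sample(slots, extra), 25)
  }
  items
}

#' Simulate the full crossover cohort
#'
#' Generates the subject table (covariates drawn from truncated normals with
#' the configured per-gender means/SDs, balanced block-randomized treatment
#' order) and two ROI time-series per subject, then — when outcome links are
#' planted — regenerates the clinical outcomes as linear functions of the
#' noise-free per-subject node difference scores via [plant_outcome()].
#'
#' @param config Pipeline configuration, see [default_config()].
#' @param seed Master seed; every random draw in the cohort derives from it.
#' @return A list of class `oxynet_cohort`: `subjects` (data.frame),
#'   `series` (named list of `roi_timeseries`, names `<subject>_v<visit>`),
#'   `base_cov`, and `truth` (the effect specification plus the noise-free
#'   delta table and planted outcome R-squared when links exist).
#' @export
simulate_cohort <- function(config = default_config(), seed = 1) {
  validate_config(config)
  if (config$n_female + config$n_male < 1 || config$n_time < 8)
    stop("nonpositive group size or series length")
  set.seed(seed)
  subjects <- simulate_subjects(config)
  base_cov <- build_base_cov(config)
  n <- nrow(subjects)
  sv_seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * n), n, 2)
  po_seed <- sample.int(.Machine$integer.max - 1, 1)

  series <- vector("list", 2 * n)
  names(series) <- paste0(rep(subjects$subject_id, each = 2), "_v", 1:2)
  for (i in seq_len(n)) {
    for (v in 1:2) {
      series[[2 * (i - 1) + v]] <- simulate_timeseries(
        subjects[i, ], v, config$effects, base_cov, config,
        seed = sv_seeds[i, v])
    }
  }

  truth <- config$effects
  links <- truth$outcome_links
  if (!is.null(links) && nrow(links)) {
    deltas_truth <- true_node_deltas(subjects, config, base_cov)
    subjects <- plant_outcome(subjects, deltas_truth, links,
                              seed = po_seed, noise_sd = truth$noise_sd)
    truth$deltas_truth <- deltas_truth
    truth$planted_r2 <- attr(subjects, "planted_r2")
  }

  structure(list(subjects = subjects, series = series,
                 base_cov = base_cov, truth = truth, seed = seed),
            class = "oxynet_cohort")
}

#' Noise-free node difference scores implied by the planted effects
#'
#' For each subject, computes eigenvector centrality and signed clustering
#' coefficient on the population partial-correlation matrices of the two
#' conditions (base covariance, and base covariance perturbed by the
#' subject's gender-specific treatment effects scaled by the subject's
#' response multiplier) and returns the placebo-minus-drug differences.
#'
#' @inheritParams simulate_cohort
#' @param subjects Subject table from [simulate_cohort()].
#' @param base_cov Population base covariance.
#' @return Long data.frame: `subject_id`, `node_id`, `metric`, `delta`.
#' @export
true_node_deltas <- function(subjects, config, base_cov = build_base_cov(config)) {
  pop_metrics <- function(covm) {
    w <- partial_correlation(list(covariance = unclass(covm), lambda = 0))
    list(ec = eigenvector_centrality(w, mode = config$ec_mode)$centrality,
         cc = clustering_coefficient_signed(w))
  }
  base_m <- pop_metrics(base_cov)
  nodes <- rownames(base_cov)
  out <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    mets <- lapply(c(PBO = "PBO", OXY = "OXY"), function(cond) {
      te <- config$effects$treatment_effects
      hit <- any(te$gender == s$gender & te$condition == cond)
      if (!hit) return(base_m)
      pop_metrics(condition_cov(base_cov, config$effects, s$gender, cond,
                                mult = s$response_mult))
    })
    out[[i]] <- data.frame(
      subject_id = s$subject_id,
      node_id = rep(nodes, 2),
      metric = rep(c("ec", "cc"), each = length(nodes)),
      delta = c(mets$PBO$ec - mets$OXY$ec, mets$PBO$cc - mets$OXY$cc),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Plant outcome-delta associations into the subject table
#'
#' Regenerates the linked clinical outcomes (CTQ total, years of use) as
#' linear functions of the standardized planted node difference scores plus
#' Gaussian noise, preserving each gender group's sample mean and spread.
#' The realized ground-truth R-squared per (outcome, gender) group is
#' attached as attribute `planted_r2`.
#'
#' @param subjects Subject table.
#' @param deltas_truth Long delta table (`subject_id`, `node_id`, `metric`,
#'   `delta`), e.g. from [true_node_deltas()] or measured deltas.
#' @param links data.frame with columns `outcome`, `gender`, `node_id`,
#'   `metric`, `slope` (slope applies to the standardized delta).
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise SD on the standardized scale.
#' @return The updated subject table with attribute `planted_r2`.
#' @export
plant_outcome <- function(subjects, deltas_truth, links, seed = NULL,
                          noise_sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(is.finite(links$slope)))
  bad <- setdiff(links$node_id, unique(deltas_truth$node_id))
  if (length(bad))
    stop("outcome links reference nodes absent from the delta table: ",
         paste(bad, collapse = ", "))
  r2 <- c()
  keys <- unique(links[c("outcome", "gender")])
  for (gi in seq_len(nrow(keys))) {
    key <- keys[gi, ]
    lk <- links[links$outcome == key$outcome & links$gender == key$gender, ,
                drop = FALSE]
    idx <- which(subjects$gender == key$gender)
    if (!length(idx)) next
    ids <- subjects$subject_id[idx]
    lin <- rep(0, length(idx))
    for (k in seq_len(nrow(lk))) {
      d <- deltas_truth$delta[match(
        paste(ids, lk$node_id[k], lk$metric[k]),
        paste(deltas_truth$subject_id, deltas_truth$node_id,
              deltas_truth$metric))]
      if (anyNA(d)) stop("missing delta for linked node ", lk$node_id[k])
      z <- if (sd(d) > 0) (d - mean(d)) / sd(d) else {
        warning("constant planted delta for node ", lk$node_id[k],
                "; link carries no signal")
        rep(0, length(d))
      }
      lin <- lin + lk$slope[k] * z
    }
    ystd <- lin + rnorm(length(idx), sd = noise_sd)
    col <- if (key$outcome == "CTQ") "ctq_total" else "years_use"
    m <- mean(subjects[[col]][idx]); s <- sd(subjects[[col]][idx])
    y <- if (sd(ystd) > 0) m + s * (ystd - mean(ystd)) / sd(ystd) else
      rep(m, length(idx))
    if (col == "ctq_total") {
      y <- pmin(pmax(round(y), 25), 125)
      subjects$ctq_total[idx] <- y
      subjects$ctq_items[idx] <- I(lapply(y, ctq_items_from_total))
    } else {
      subjects$years_use[idx] <- round(pmax(y, 0), 1)
    }
    r2[paste(key$outcome, key$gender, sep = "_")] <-
      var(lin) / (var(lin) + noise_sd^2)
  }
  attr(subjects, "planted_r2") <- r2
  subjects
}
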