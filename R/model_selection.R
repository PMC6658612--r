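#' Robust outlier trimming of the outcome
#'
#' Removes observations whose outcome lies beyond `k` robust standard
#' deviations of the median (robust SD = 1.4826 x MAD). A warning is raised
#' if more than 20% of observations are trimmed.
#'
#' @param X Predictor matrix or data.frame.
#' @param y Outcome vector.
#' @param k Trimming multiple.
#' @param enabled Set `FALSE` to disable trimming (identity).
#' @return List with trimmed `X`, `y` and `removed` (original indices).
#' @export
trim_outliers <- function(X, y, k = 3, enabled = TRUE) {
  if (length(y) < 10) stop("need at least 10 observations")
  if (!enabled)
    return(list(X = X, y = y, removed = integer(0)))
  s <- mad(y)
  keep <- if (s > 0) abs(y - median(y)) <= k * s else rep(TRUE, length(y))
  if (mean(!keep) > 0.2)
    warning("outlier trimming removed more than 20% of observations")
  list(X = X[keep, , drop = FALSE], y = y[keep], removed = which(!keep))
}

#' One best-subsets replication
#'
#' Splits the sample into a training partition (`split_fraction`) and a
#' held-out overfit-prevention partition, enumerates every predictor subset
#' up to `max_subset_size` by OLS on the training partition, selects the
#' subset with the smallest held-out average squared error (ASE), then
#' refits the selected subset to report adjusted R-squared, the overall
#' model F-test p-value, AIC, coefficients and leave-one-out importance.
#'
#' The reporting refit uses the training partition by default
#' (`refit = "train"`): selection is driven entirely by the held-out data,
#' so the training-partition F-test of the selected subset stays calibrated
#' under the null. `refit = "full"` refits on the whole replicate sample.
#'
#' @param X Subject x predictor matrix or data.frame (at most 21 predictors).
#' @param y Outcome vector (at least 10 subjects).
#' @param split_fraction Training share of the sample.
#' @param max_subset_size Largest subset enumerated.
#' @param seed Optional seed for the split.
#' @param refit `"train"` or `"full"`.
#' @param replication_id Identifier carried into the result.
#' @param train_index Optional explicit training indices (overrides the
#'   random split; mainly for reproducing a given partition).
#' @return A list of class `replication_result`: `replication_id`,
#'   `selected_subset`, `train_index`, `test_index`, `test_ase`,
#'   `adjusted_r2`, `model_p`, `aic`, `coefficients`, `importance`.
#' @export
best_subsets_fit <- function(X, y, split_fraction = 0.7, max_subset_size = 5,
                             seed = NULL, refit = c("train", "full"),
                             replication_id = 1L, train_index = NULL) {
  refit <- match.arg(refit)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 10) stop("need at least 10 subjects")
  if (ncol(X) > 21) stop("at most 21 candidate predictors are supported")
  if (length(y) != n) stop("X and y sizes disagree")
  if (!is.null(seed)) set.seed(seed)
  tr <- if (!is.null(train_index)) sort(train_index) else
    sort(sample(n, round(split_fraction * n)))
  te <- setdiff(seq_len(n), tr)
  if (length(te) < 3) stop("held-out partition smaller than 3 subjects")
  sel <- bs_search_cpp(X[tr, , drop = FALSE], y[tr],
                       X[te, , drop = FALSE], y[te], max_subset_size)
  if (!length(sel$subset)) stop("no estimable subset found")
  subset <- colnames(X)[sel$subset]
  fit_idx <- if (refit == "train") tr else seq_len(n)
  dat <- data.frame(y = y[fit_idx],
                    X[fit_idx, subset, drop = FALSE], check.names = FALSE)
  fit <- lm(y ~ ., data = dat)
  sm <- summary(fit)
  fs <- sm$fstatistic
  structure(list(
    replication_id = replication_id,
    selected_subset = subset,
    train_index = tr, test_index = te,
    test_ase = sel$ase,
    adjusted_r2 = sm$adj.r.squared,
    model_p = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    aic = AIC(fit),
    coefficients = coef(fit),
    importance = loo_importance(fit)),
    class = "replication_result")
}

#' Leave-one-out predictor importance
#'
#' Importance of each predictor in a fitted linear model: the increase in
#' residual sum of squares when that predictor alone is removed, normalized
#' so the importances sum to 1 (all nonnegative). A single-predictor model
#' has importance 1.
#'
#' @param fit An `lm` fit with at least one predictor.
#' @return Named numeric vector summing to 1.
#' @export
loo_importance <- function(fit) {
  preds <- attr(terms(fit), "term.labels")
  if (!length(preds)) stop("model has no predictors")
  if (length(preds) == 1) return(setNames(1, preds))
  mm <- model.matrix(fit)
  assign <- attr(mm, "assign")
  y <- model.response(model.frame(fit))
  rss_full <- sum(resid(fit)^2)
  inc <- vapply(seq_along(preds), function(k) {
    keep <- assign != k
    rk <- lm.fit(mm[, keep, drop = FALSE], y)
    max(sum(rk$residuals^2) - rss_full, 0)
  }, numeric(1))
  names(inc) <- preds
  if (sum(inc) <= 0) return(setNames(rep(1 / length(preds), length(preds)),
                                     preds))
  inc / sum(inc)
}

#' Replicated best-subsets selection
#'
#' Runs [best_subsets_fit()] over `n_replications` replicate samples,
#' accumulates each predictor's leave-one-out importance across
#' replications (each replication contributes exactly 1 in total), marks
#' the predictors whose cumulative importance exceeds
#' `importance_threshold` as the final set, and fits the final simultaneous
#' model with VIF-based collinearity pruning via [finalize_with_vif()].
#'
#' Replicates are fresh random train/holdout partitions of the cohort by
#' default (`resample = "partition"`); `resample = "bootstrap"` instead
#' draws a with-replacement resample of size n before splitting (that
#' variant leaks duplicated subjects across the split and is
#' anti-conservative — see the package vignette). Outliers are trimmed per
#' replication before fitting.
#'
#' @inheritParams best_subsets_fit
#' @param n_replications Number of replications.
#' @param seed Master seed for the whole selection run.
#' @param resample `"partition"` or `"bootstrap"`.
#' @param trim,trim_k Outlier trimming switch and multiple.
#' @param importance_threshold Cumulative importance cut for the final set.
#' @param vif_threshold VIF above which collinearity pruning triggers.
#' @param alpha Significance level used to count significant replications.
#' @return A list of class `selection_summary`: `replications`,
#'   `cumulative_importance`, `final_predictors`, `final_model`, `vif`,
#'   `n_significant`, `mean_adjusted_r2`, `seed`.
#' @export
replicate_selection <- function(X, y, n_replications = 10, seed = NULL,
                                split_fraction = 0.7, max_subset_size = 5,
                                resample = c("partition", "bootstrap"),
                                refit = c("train", "full"),
                                trim = TRUE, trim_k = 3,
                                importance_threshold = 1,
                                vif_threshold = 4, alpha = 0.05) {
  resample <- match.arg(resample)
  refit <- match.arg(refit)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    idx <- if (resample == "bootstrap") sample(n, n, replace = TRUE)
           else seq_len(n)
    tm <- trim_outliers(X[idx, , drop = FALSE], y[idx], k = trim_k,
                        enabled = trim)
    reps[[r]] <- best_subsets_fit(tm$X, tm$y,
                                  split_fraction = split_fraction,
                                  max_subset_size = max_subset_size,
                                  refit = refit, replication_id = r)
  }
  cum <- setNames(rep(0, ncol(X)), colnames(X))
  for (r in reps) cum[names(r$importance)] <- cum[names(r$importance)] +
    r$importance
  finals <- names(cum)[cum > importance_threshold]
  final_model <- NULL
  vif <- NULL
  if (length(finals)) {
    fin <- finalize_with_vif(X[, finals, drop = FALSE], y,
                             vif_threshold = vif_threshold)
    final_model <- fin
    vif <- fin$vif
  }
  ps <- vapply(reps, function(r) r$model_p, numeric(1))
  structure(list(
    replications = reps,
    cumulative_importance = cum,
    final_predictors = finals,
    final_model = final_model,
    vif = vif,
    n_significant = sum(ps <= alpha),
    mean_adjusted_r2 = mean(vapply(reps, function(r) r$adjusted_r2,
                                   numeric(1))),
    seed = seed),
    class = "selection_summary")
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from regressing predictor
#' `k` on the remaining predictors; a single predictor has VIF 1 and exact
#' collinearity yields `Inf`.
#'
#' @param X Predictor matrix with at least one column.
#' @return Named numeric vector.
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 1) return(setNames(1, colnames(X)))
  vif <- vapply(seq_len(p), function(k) {
    fit <- lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, k] - mean(X[, k]))^2)
    r2 <- if (tss > 0) 1 - rss / tss else 1
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(vif, colnames(X))
}

#' Final simultaneous model with VIF pruning
#'
#' Fits the simultaneous OLS model on all final predictors and computes
#' their VIFs. While any VIF exceeds the threshold, the collinear cluster is
#' resolved by keeping the member whose solo inclusion yields the highest
#' adjusted R-squared, dropping the rest, refitting and recomputing VIFs.
#'
#' @param X Predictor matrix restricted to the final predictors.
#' @param y Outcome vector.
#' @param vif_threshold Pruning threshold.
#' @return List: `predictors`, `dropped`, `coefficients`, `adjusted_r2`,
#'   `model_p`, `aic`, `vif`, `fit` (the `lm` object).
#' @export
finalize_with_vif <- function(X, y, vif_threshold = 4) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("need at least one final predictor")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  dropped <- character(0)
  repeat {
    vif <- compute_vif(X)
    high <- names(vif)[vif > vif_threshold]
    if (!length(high)) break
    solo_r2 <- vapply(high, function(p) {
      summary(lm(y ~ X[, p]))$adj.r.squared
    }, numeric(1))
    keep <- high[which.max(solo_r2)]
    out <- setdiff(high, keep)
    if (!length(out)) break
    dropped <- c(dropped, out)
    X <- X[, setdiff(colnames(X), out), drop = FALSE]
  }
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- lm(y ~ ., data = dat)
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(predictors = colnames(X), dropped = dropped,
       coefficients = coef(fit),
       adjusted_r2 = sm$adj.r.squared,
       model_p = if (!is.null(fs))
         unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)) else NA_real_,
       aic = AIC(fit),
       vif = compute_vif(X),
       fit = fit)
}

#' Full model sweep over outcomes, genders and metrics
#'
#' Runs [replicate_selection()] for every combination of outcome (CTQ,
#' YRSUSE), gender and graph metric (ec, cc) — eight models — with the 20
#' node difference scores plus head motion as candidate predictors, and
#' compares the two metrics per (outcome, gender) cell: the metric with
#' more significant replications wins (ties broken by mean adjusted
#' R-squared).
#'
#' @param deltas Delta table from [compute_deltas()] (already restricted to
#'   the nodes of interest).
#' @param subjects Subject table with `ctq_total`, `years_use`,
#'   `head_motion`, `gender`.
#' @param config Pipeline configuration.
#' @param seed Master seed for the sweep.
#' @return A list of class `model_sweep`: `models` (named list of
#'   `selection_summary`, names `<outcome>_<gender>_<metric>`) and
#'   `comparison` (data.frame per outcome x gender with the winning metric).
#' @export
run_model_sweep <- function(deltas, subjects, config = default_config(),
                            seed = 1) {
  set.seed(seed)
  models <- list()
  for (outcome in c("CTQ", "YRSUSE")) {
    for (gender in c("female", "male")) {
      for (metric in c("ec", "cc")) {
        sub <- subjects[subjects$gender == gender, , drop = FALSE]
        Xd <- delta_matrix(deltas, metric, sub$subject_id)
        X <- cbind(Xd, head_motion = sub$head_motion[
          match(rownames(Xd), sub$subject_id)])
        ycol <- if (outcome == "CTQ") "ctq_total" else "years_use"
        y <- sub[[ycol]][match(rownames(Xd), sub$subject_id)]
        models[[paste(outcome, gender, metric, sep = "_")]] <-
          replicate_selection(
            X, y,
            n_replications = config$n_replications,
            split_fraction = config$split_fraction,
            max_subset_size = config$max_subset_size,
            resample = config$resample, refit = config$refit,
            trim = config$trim, trim_k = config$trim_k,
            importance_threshold = config$importance_threshold,
            vif_threshold = config$vif_threshold,
            alpha = config$fdr_q)
      }
    }
  }
  comp <- do.call(rbind, lapply(c("CTQ", "YRSUSE"), function(outcome)
    do.call(rbind, lapply(c("female", "male"), function(gender) {
      m <- models[[paste(outcome, gender, "ec", sep = "_")]]
      c2 <- models[[paste(outcome, gender, "cc", sep = "_")]]
      win <- if (m$n_significant > c2$n_significant) "ec"
        else if (c2$n_significant > m$n_significant) "cc"
        else if (m$mean_adjusted_r2 >= c2$mean_adjusted_r2) "ec" else "cc"
      data.frame(outcome = outcome, gender = gender,
                 ec_significant = m$n_significant,
                 cc_significant = c2$n_significant,
                 ec_mean_adj_r2 = m$mean_adjusted_r2,
                 cc_mean_adj_r2 = c2$mean_adjusted_r2,
                 better_metric = win, stringsAsFactors = FALSE)
    }))))
  structure(list(models = models, comparison = comp, seed = seed),
            class = "model_sweep")
}

# wide subject x node matrix of difference scores for one metric
delta_matrix <- function(deltas, metric, subject_ids = NULL) {
  d <- deltas[deltas$metric == metric, , drop = FALSE]
  if (!is.null(subject_ids))
    d <- d[d$subject_id %in% subject_ids, , drop = FALSE]
  nodes <- sort(unique(d$node_id))
  subs <- unique(d$subject_id)
  m <- matrix(NA_real_, length(subs), length(nodes),
              dimnames = list(subs, nodes))
  m[cbind(match(d$subject_id, subs), match(d$node_id, nodes))] <- d$delta
  m[complete.cases(m), , drop = FALSE]
}
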