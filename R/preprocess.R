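#' Nuisance regression of global-signal and motion regressors
#'
#' Replaces each node's series by the residuals of an ordinary least-squares
#' regression on an intercept, the three tissue-mean global signals and the
#' six head-motion parameters. Collinear (rank-deficient) columns of the
#' design are dropped with a warning.
#'
#' @param series A `roi_timeseries` (see [simulate_timeseries()]), or a
#'   node x time matrix if `global_signals`/`motion_params` are supplied.
#' @param global_signals,motion_params Optional regressor matrices
#'   (rows = regressors, columns = time) when `series` is a plain matrix.
#' @return Node x time residual matrix.
#' @export
regress_nuisance <- function(series, global_signals = NULL,
                             motion_params = NULL) {
  if (inherits(series, "roi_timeseries")) {
    signal <- series$signal
    global_signals <- series$global_signals
    motion_params <- series$motion_params
  } else signal <- series
  n_time <- ncol(signal)
  X <- cbind(intercept = 1,
             if (!is.null(global_signals)) t(global_signals),
             if (!is.null(motion_params)) t(motion_params))
  if (nrow(X) != n_time)
    stop("regressor length does not match the signal's time dimension")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[(qx$rank + 1):ncol(X)]
    warning("dropping ", length(drop), " collinear nuisance column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    qx <- qr(X[, -drop, drop = FALSE])
  }
  res <- t(qr.resid(qx, t(signal)))
  dimnames(res) <- dimnames(signal)
  res
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`) to each node's series.
#'
#' @param signal Node x time matrix.
#' @param tr_seconds Sampling interval in seconds.
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz <` Nyquist.
#' @return Filtered node x time matrix.
#' @export
bandpass_filter <- function(signal, tr_seconds, low_hz = 0.009,
                            high_hz = 0.08) {
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist))
    stop("band edges must satisfy 0 < low < high < Nyquist (",
         signif(nyquist, 3), " Hz)")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  out <- t(apply(signal, 1, function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- dimnames(signal)
  out
}

#' Temporal censoring of corrupt time points
#'
#' For every corrupt time point `t`, removes the window
#' `{t - pre, ..., t + post}` (default one preceding and two following
#' points), clipped at the series boundaries; windows from multiple corrupt
#' points are unioned and the surviving column order is preserved.
#'
#' @param signal Node x time matrix.
#' @param corrupt_mask Logical vector over time.
#' @param pre,post Window extent before/after each corrupt point.
#' @return List with `signal` (censored matrix) and `retained_index`
#'   (strictly increasing original time indices kept).
#' @export
censor_timepoints <- function(signal, corrupt_mask, pre = 1, post = 2) {
  n_time <- ncol(signal)
  if (length(corrupt_mask) != n_time)
    stop("corrupt_mask length must equal the signal's time dimension")
  bad <- which(corrupt_mask)
  drop <- unique(unlist(lapply(bad, function(t)
    max(1, t - pre):min(n_time, t + post))))
  keep <- setdiff(seq_len(n_time), drop)
  if (!length(keep))
    message("censoring removed every time point")
  list(signal = signal[, keep, drop = FALSE], retained_index = keep)
}

#' Full ROI-level cleaning of one subject-visit
#'
#' Applies the pipeline order regress -> band-pass -> censor (the filter
#' requires a contiguous time grid, so censoring comes last) and returns the
#' analysis-ready series.
#'
#' @param series A `roi_timeseries`.
#' @param config Pipeline configuration, see [default_config()].
#' @return A list of class `clean_series`: `subject_id`, `visit`,
#'   `condition`, `signal`, `retained_index`, `scrub_fraction` and `order`
#'   (the stage order applied, recorded for the run manifest).
#' @export
preprocess_series <- function(series, config = default_config()) {
  stopifnot(inherits(series, "roi_timeseries"))
  n_time <- ncol(series$signal)
  res <- regress_nuisance(series)
  flt <- bandpass_filter(res, series$tr_seconds,
                         config$band_low, config$band_high)
  cen <- censor_timepoints(flt, series$corrupt_mask,
                           config$censor_pre, config$censor_post)
  structure(list(subject_id = series$subject_id, visit = series$visit,
                 condition = series$condition, signal = cen$signal,
                 retained_index = cen$retained_index,
                 scrub_fraction = 1 - length(cen$retained_index) / n_time,
                 order = c("regress", "bandpass", "censor")),
            class = "clean_series")
}
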