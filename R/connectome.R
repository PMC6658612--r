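#' Shrinkage covariance with a diagonal target
#'
#' Estimates the node covariance of a node x time signal and shrinks it
#' toward its own diagonal, `(1 - lambda) * S + lambda * diag(S)`, with the
#' mixing parameter `lambda` set by the analytic (Ledoit-Wolf style)
#' optimal intensity for the diagonal target: the ratio of the summed
#' estimated variances of the off-diagonal correlations to their summed
#' squares, clipped to `[0, 1]`. With many more nodes than retained time
#' points the sample covariance is singular, so a positive `lambda` is what
#' makes the matrix well conditioned and invertible.
#'
#' @param signal Node x time matrix (at least 3 time points).
#' @param lambda Optional manual override of the mixing parameter in
#'   `[0, 1]`; `NULL` (default) uses the analytic estimate.
#' @param standardize Z-score each node over the retained time points before
#'   estimation (making the covariance a correlation matrix); default `TRUE`.
#' @return A list of class `shrinkage_cov`: `covariance`, `lambda`,
#'   `target = "diagonal"`, `n_obs`.
#' @export
shrink_covariance <- function(signal, lambda = NULL, standardize = TRUE) {
  n_time <- ncol(signal)
  if (n_time < 3) stop("need at least 3 retained time points")
  if (!is.null(lambda) && (lambda < 0 || lambda > 1))
    stop("lambda must lie in [0, 1]")
  x <- t(signal)                       # observations x nodes
  sdv <- apply(x, 2, sd)
  zero <- sdv < .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " constant node(s); variance floored at machine ",
            "epsilon")
    sdv[zero] <- sqrt(.Machine$double.eps)
  }
  if (standardize) {
    x <- scale(x, center = TRUE, scale = sdv)
    sdv <- rep(1, ncol(x))
  } else {
    x <- scale(x, center = TRUE, scale = FALSE)
  }
  S <- crossprod(x) / (n_time - 1)
  if (any(zero)) diag(S) <- pmax(diag(S), .Machine$double.eps)
  if (is.null(lambda)) {
    # analytic intensity for the diagonal target, on the correlation scale
    sdx <- apply(x, 2, sd)
    sdx[sdx < .Machine$double.eps] <- 1   # constant nodes contribute zero
    xs <- scale(x, center = FALSE, scale = sdx)
    wbar <- crossprod(xs) / n_time                # mean of w_kij
    w2 <- crossprod(xs^2)                         # sum_k w_kij^2
    varr <- n_time / (n_time - 1)^3 * (w2 - n_time * wbar^2)
    r <- n_time / (n_time - 1) * wbar
    off <- upper.tri(r)
    denom <- sum(r[off]^2)
    lambda <- if (denom > 0) sum(varr[off]) / denom else 1
    lambda <- min(max(lambda, 0), 1)
  }
  covm <- (1 - lambda) * S
  diag(covm) <- diag(S)
  dimnames(covm) <- list(rownames(signal), rownames(signal))
  structure(list(covariance = covm, lambda = lambda, target = "diagonal",
                 n_obs = n_time),
            class = "shrinkage_cov")
}

#' Partial-correlation connectivity matrix
#'
#' Inverts the (shrunk) covariance and normalizes the precision matrix `P`
#' into partial correlations, `w_ij = -P_ij / sqrt(P_ii * P_jj)`; the
#' diagonal is set to zero and residual numerical asymmetry is averaged out.
#' The result is the weighted, signed adjacency matrix of a fully connected
#' undirected graph.
#'
#' @param cov A `shrinkage_cov` (or any list with a `covariance` element, or
#'   a plain covariance matrix).
#' @return N x N signed weight matrix with zero diagonal and node-id
#'   dimnames.
#' @export
partial_correlation <- function(cov) {
  covm <- if (is.list(cov)) cov$covariance else cov
  P <- tryCatch(solve(covm), error = function(e)
    stop("covariance is singular; increase the shrinkage intensity"))
  d <- sqrt(diag(P))
  W <- -P / tcrossprod(d)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W[W > 1] <- 1
  W[W < -1] <- -1
  dimnames(W) <- dimnames(covm)
  W
}

#' Connectome from a cleaned series
#'
#' Convenience wrapper: shrinkage covariance (analytic or configured
#' `lambda`) followed by partial correlation.
#'
#' @param clean A `clean_series` (see [preprocess_series()]) or node x time
#'   matrix.
#' @param config Pipeline configuration.
#' @return Weight matrix with attribute `lambda`.
#' @export
build_connectome <- function(clean, config = default_config()) {
  signal <- if (inherits(clean, "clean_series")) clean$signal else clean
  sc <- shrink_covariance(signal, lambda = config$lambda,
                          standardize = config$standardize)
  W <- partial_correlation(sc)
  attr(W, "lambda") <- sc$lambda
  W
}
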