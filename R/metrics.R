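#' Eigenvector centrality of a signed weighted network
#'
#' Node-level global influence: the elementwise absolute value of the
#' unit-Euclidean-norm eigenvector belonging to the principal eigenvalue of
#' the adjacency matrix (the eigenvalue of largest magnitude). On a signed
#' matrix "principal" is taken as largest `|lambda|` of the signed matrix
#' itself; `mode = "absolute"` instead computes the centrality on `|M|` as a
#' sensitivity variant.
#'
#' @param M Symmetric weight matrix.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @param tol Tolerance for flagging a degenerate principal eigenspace.
#' @return A list of class `spectral_result`: `eigenvalue` (the principal
#'   eigenvalue), `eigenvector` (unit norm), `centrality` (nonnegative,
#'   named by node).
#' @export
eigenvector_centrality <- function(M, mode = c("signed", "absolute"),
                                   tol = 1e-10) {
  mode <- match.arg(mode)
  if (!isSymmetric(unname(M), tol = 1e-8))
    stop("adjacency matrix must be symmetric")
  if (any(!is.finite(M))) stop("adjacency matrix must be finite")
  A <- if (mode == "absolute") abs(M) else M
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  k <- which.max(abs(eig$values))
  # degenerate principal magnitude: prefer the positive eigenvalue, then
  # break remaining ties deterministically by lexicographic |eigenvector|
  ties <- which(abs(abs(eig$values) - abs(eig$values[k])) < tol)
  if (length(ties) > 1) {
    pos <- ties[eig$values[ties] >= eig$values[ties][1] - tol]
    if (length(pos) < length(ties)) ties <- pos else
      warning("principal eigenvalue has multiplicity ", length(ties),
              " within tolerance; choosing deterministically")
    cand <- abs(eig$vectors[, ties, drop = FALSE])
    ord <- do.call(order, as.data.frame(-t(cand)))
    k <- ties[ord[1]]
  }
  v <- eig$vectors[, k]
  v <- v / sqrt(sum(v^2))
  structure(list(eigenvalue = eig$values[k], eigenvector = v,
                 centrality = setNames(abs(v), rownames(M))),
            class = "spectral_result")
}

#' Signed weighted clustering coefficient
#'
#' Local influence of each node: the sum of signed triangle products around
#' the node over the maximum magnitude that sum could attain,
#' `CC_i = sum_{j != q} w_ij w_iq w_jq / sum_{j != q} |w_ij w_iq|`
#' (indices distinct from `i`). In the binary limit this is the fraction of
#' a node's neighbor pairs that are themselves connected. Nodes with a zero
#' denominator (no two incident edges) get 0.
#'
#' @param M Symmetric weight matrix with zero diagonal.
#' @return Named numeric vector in `[-1, 1]`.
#' @export
clustering_coefficient_signed <- function(M) {
  if (!isSymmetric(unname(M), tol = 1e-8))
    stop("adjacency matrix must be symmetric")
  if (any(abs(diag(M)) > 1e-12))
    stop("adjacency matrix must have a zero diagonal")
  W <- M
  diag(W) <- 0
  num <- diag(W %*% W %*% W)       # ordered (j, q) pairs; diagonal kills j=q
  srow <- rowSums(abs(W))
  den <- srow^2 - rowSums(W^2)     # sum_{j != q} |w_ij| |w_iq|
  cc <- ifelse(den > .Machine$double.eps, num / den, 0)
  setNames(cc, rownames(M))
}

#' Node-metric table for a cohort of connectomes
#'
#' Computes eigenvector centrality and the signed clustering coefficient on
#' every full subject-visit connectivity matrix (metrics always use the
#' whole graph; any ROI restriction downstream selects rows of this table
#' rather than recomputing on a subgraph) and resolves visit numbers to
#' treatment conditions.
#'
#' @param matrices Named list of weight matrices, names `<subject>_v<visit>`.
#' @param subjects Subject table with `visit1_condition`/`visit2_condition`.
#' @param ec_mode Passed to [eigenvector_centrality()].
#' @return Long data.frame: `subject_id`, `condition`, `node_id`, `metric`
#'   (`ec`/`cc`), `value`. Subjects lacking either visit are excluded with a
#'   message.
#' @export
compute_metric_table <- function(matrices, subjects, ec_mode = "signed") {
  have <- function(id) paste0(id, "_v", 1:2) %in% names(matrices)
  ok <- vapply(subjects$subject_id, function(id) all(have(id)), logical(1))
  if (any(!ok))
    message("excluding ", sum(!ok), " subject(s) with a missing visit: ",
            paste(subjects$subject_id[!ok], collapse = ", "))
  subjects <- subjects[ok, , drop = FALSE]
  out <- vector("list", 2 * nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    for (v in 1:2) {
      M <- matrices[[paste0(id, "_v", v)]]
      cond <- if (v == 1) subjects$visit1_condition[i] else
        subjects$visit2_condition[i]
      nodes <- rownames(M)
      if (is.null(nodes)) nodes <- sprintf("n%03d", seq_len(nrow(M)))
      ec <- eigenvector_centrality(M, mode = ec_mode)$centrality
      cc <- clustering_coefficient_signed(M)
      out[[2 * (i - 1) + v]] <- data.frame(
        subject_id = id, condition = cond,
        node_id = rep(nodes, 2),
        metric = rep(c("ec", "cc"), each = length(nodes)),
        value = c(unname(ec), unname(cc)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
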