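#' Placebo-minus-drug difference scores
#'
#' One difference per (subject, node, metric): value in the placebo
#' condition minus value in the active condition. A positive score means
#' the drug reduced that node's connectivity measure; a negative score means
#' it increased it.
#'
#' @param metric_table Long table from [compute_metric_table()].
#' @param roi_nodes Optional character vector of node ids to restrict to
#'   (the candidate-predictor set); `NULL` keeps all nodes.
#' @param placebo,active Condition labels.
#' @return data.frame: `subject_id`, `node_id`, `metric`, `delta`. Subjects
#'   missing either condition are dropped with a message.
#' @export
compute_deltas <- function(metric_table, roi_nodes = NULL,
                           placebo = "PBO", active = "OXY") {
  tb <- metric_table
  if (!is.null(roi_nodes)) tb <- tb[tb$node_id %in% roi_nodes, , drop = FALSE]
  key <- paste(tb$subject_id, tb$node_id, tb$metric)
  pb <- tb[tb$condition == placebo, ]
  ox <- tb[tb$condition == active, ]
  m <- match(paste(pb$subject_id, pb$node_id, pb$metric),
             paste(ox$subject_id, ox$node_id, ox$metric))
  keep <- !is.na(m)
  dropped <- setdiff(unique(tb$subject_id), unique(pb$subject_id[keep]))
  if (length(dropped))
    message("dropping subject(s) without both conditions: ",
            paste(dropped, collapse = ", "))
  data.frame(subject_id = pb$subject_id[keep],
             node_id = pb$node_id[keep],
             metric = pb$metric[keep],
             delta = pb$value[keep] - ox$value[m[keep]],
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR rejections
#'
#' Step-up rule at level `q`: reject the hypotheses whose BH-adjusted
#' p-value is at most `q`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q FDR level.
#' @return Logical vector of rejections.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH") <= q
}

#' Per-node paired condition contrast within one gender
#'
#' Two-sided paired t-test of active versus placebo per (node, metric) for
#' the subjects of the requested gender; p-values are pooled per metric
#' family across the nodes and flagged by BH-FDR at level `q`.
#'
#' @param metric_table Long table from [compute_metric_table()].
#' @param subjects Subject table (for gender lookup).
#' @param gender `"female"` or `"male"`.
#' @param roi_nodes Optional restriction to the nodes of interest.
#' @param q FDR level.
#' @return data.frame: `gender`, `node_id`, `metric`, `statistic`, `df`,
#'   `p_value`, `q_flag`, `mean_delta` (placebo minus active).
#' @export
paired_condition_contrast <- function(metric_table, subjects, gender,
                                      roi_nodes = NULL, q = 0.05) {
  ids <- subjects$subject_id[subjects$gender == gender]
  if (length(ids) < 3) stop("need at least 3 subjects of gender ", gender)
  deltas <- compute_deltas(metric_table[metric_table$subject_id %in% ids, ],
                           roi_nodes = roi_nodes)
  cells <- unique(deltas[c("node_id", "metric")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    d <- deltas$delta[deltas$node_id == cells$node_id[i] &
                        deltas$metric == cells$metric[i]]
    if (sd(d) < .Machine$double.eps) {
      warning("zero-variance differences for node ", cells$node_id[i],
              " (", cells$metric[i], "); p set to 1")
      data.frame(statistic = 0, df = length(d) - 1, p_value = 1,
                 mean_delta = mean(d))
    } else {
      tt <- t.test(d)
      data.frame(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value, mean_delta = mean(d))
    }
  })
  out <- cbind(gender = gender, cells, do.call(rbind, res))
  out$q_flag <- FALSE
  for (m in unique(out$metric))
    out$q_flag[out$metric == m] <- fdr_bh(out$p_value[out$metric == m], q)
  rownames(out) <- NULL
  out
}

#' Covariate screening of difference scores and metrics
#'
#' Runs the standard nuisance screens with FDR control per (metric, family):
#' Welch t-tests comparing the placebo-minus-drug difference score between
#' the two levels of each binary covariate (scanner, smoker), and
#' Spearman rank correlations of each continuous covariate (head motion and
#' the per-visit subjective ratings) against the metric values by node,
#' metric, gender and condition.
#'
#' @param deltas Delta table from [compute_deltas()].
#' @param metric_table Long metric table.
#' @param subjects Subject table.
#' @param binary Character vector of binary covariate columns.
#' @param continuous Character vector of continuous covariate columns;
#'   columns `<name>_v1`/`<name>_v2` are matched to the visit of the scanned
#'   condition, plain columns are used as-is.
#' @param q FDR level.
#' @return data.frame: `family`, `covariate`, `gender`, `condition`,
#'   `node_id`, `metric`, `statistic`, `p_value`, `q_flag`.
#' @export
covariate_screens <- function(deltas, metric_table, subjects,
                              binary = c("scanner", "smoker"),
                              continuous = c("head_motion", "craving",
                                             "anxiety", "stress", "stai",
                                             "ccq"),
                              q = 0.05) {
  rows <- list()
  for (cv in binary) {
    g <- subjects[[cv]][match(deltas$subject_id, subjects$subject_id)]
    lv <- unique(g[!is.na(g)])
    if (length(lv) < 2 || min(table(g)) < 2) {
      warning("covariate ", cv, " has fewer than 2 populated levels; skipped")
      next
    }
    cells <- unique(deltas[c("node_id", "metric")])
    for (i in seq_len(nrow(cells))) {
      sel <- deltas$node_id == cells$node_id[i] &
        deltas$metric == cells$metric[i]
      d <- deltas$delta[sel]; gg <- g[sel]
      if (sd(d) < .Machine$double.eps) {
        st <- 0; pv <- 1
      } else {
        tt <- t.test(d ~ gg, var.equal = FALSE)
        st <- unname(tt$statistic); pv <- tt$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        family = paste0(cv, "_welch"), covariate = cv, gender = "all",
        condition = "delta", node_id = cells$node_id[i],
        metric = cells$metric[i], statistic = st, p_value = pv,
        stringsAsFactors = FALSE)
    }
  }
  for (cv in continuous) {
    per_visit <- paste0(cv, "_v1") %in% names(subjects)
    if (!per_visit && !cv %in% names(subjects)) next
    for (g in unique(subjects$gender)) {
      for (cond in unique(metric_table$condition)) {
        sub <- subjects[subjects$gender == g, ]
        mt <- metric_table[metric_table$condition == cond &
                             metric_table$subject_id %in% sub$subject_id, ]
        visit <- ifelse(sub$visit1_condition == cond, 1L, 2L)
        xval <- if (per_visit)
          ifelse(visit == 1L, sub[[paste0(cv, "_v1")]],
                 sub[[paste0(cv, "_v2")]])
        else sub[[cv]]
        names(xval) <- sub$subject_id
        if (sd(xval) < .Machine$double.eps) {
          warning("constant covariate ", cv, " for ", g, "/", cond,
                  "; skipped")
          next
        }
        cells <- unique(mt[c("node_id", "metric")])
        for (i in seq_len(nrow(cells))) {
          sel <- mt$node_id == cells$node_id[i] &
            mt$metric == cells$metric[i]
          y <- mt$value[sel]
          x <- xval[mt$subject_id[sel]]
          ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
          rows[[length(rows) + 1]] <- data.frame(
            family = paste0(cv, "_spearman"), covariate = cv, gender = g,
            condition = cond, node_id = cells$node_id[i],
            metric = cells$metric[i], statistic = unname(ct$estimate),
            p_value = ct$p.value, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$q_flag <- FALSE
  for (fam in unique(out$family)) for (m in unique(out$metric)) {
    sel <- out$family == fam & out$metric == m
    if (any(sel)) out$q_flag[sel] <- fdr_bh(out$p_value[sel], q)
  }
  rownames(out) <- NULL
  out
}
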