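# shared fixtures, all generated in code

# node table with the 20 ROIs plus a few filler nodes, for cheap pipelines
small_nodes <- function(n_filler = 8) {
  roi <- roi_table()
  roi$type <- ifelse(roi$region_class %in% c("amygdala", "striatum"),
                     "subcortical", "cortical")
  roi$roi <- TRUE
  fill <- data.frame(
    node_id = sprintf("fill_%02d", seq_len(n_filler)),
    label = sprintf("filler %d", seq_len(n_filler)),
    x = 0, y = 0, z = 0,
    region_class = "cortex_synthetic", type = "cortical", roi = FALSE,
    stringsAsFactors = FALSE)
  rbind(roi[, names(fill)], fill)
}

small_config <- function(n_female = 10, n_male = 10, n_time = 60, ...) {
  default_config(n_female = n_female, n_male = n_male, n_time = n_time,
                 nodes = small_nodes(), ...)
}

no_effects <- function() {
  eff <- default_effects()
  eff$treatment_effects <- eff$treatment_effects[0, ]
  eff$outcome_links <- eff$outcome_links[0, ]
  eff
}

# random symmetric signed weight matrix with zero diagonal
rsym <- function(n, scale = 0.8) {
  m <- matrix(runif(n * n, -scale, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  m
}

# one-row subject stub for direct simulate_timeseries calls
subject_stub <- function(gender = "male", first = "OXY") {
  data.frame(subject_id = "S001", gender = gender,
             treatment_order = paste0(first, "_first"),
             visit1_condition = first,
             visit2_condition = setdiff(c("OXY", "PBO"), first),
             head_motion = 0.15, response_mult = 1,
             stringsAsFactors = FALSE)
}

# metric-level cohort generator: node metric values with subject baselines,
# unit condition noise, and optional paired shifts (effect size d on the
# within-subject difference, whose null SD is sqrt(2))
simulate_metric_cohort <- function(n_female = 39, n_male = 54,
                                   effects = NULL,
                                   nodes = roi_table()$node_id) {
  n <- n_female + n_male
  subjects <- data.frame(
    subject_id = sprintf("M%03d", seq_len(n)),
    gender = rep(c("female", "male"), c(n_female, n_male)),
    stringsAsFactors = FALSE)
  subjects$treatment_order <- rep_len(c("OXY_first", "PBO_first"), n)
  subjects$visit1_condition <- ifelse(subjects$treatment_order == "OXY_first",
                                      "OXY", "PBO")
  subjects$visit2_condition <- ifelse(subjects$treatment_order == "OXY_first",
                                      "PBO", "OXY")
  subjects$head_motion <- runif(n, 0.05, 0.3)
  subjects$scanner <- rep_len(c(rep("TRIO", 9), "PRISMA"), n)
  subjects$smoker <- rep_len(c(TRUE, TRUE, FALSE), n)
  grid <- expand.grid(subject_id = subjects$subject_id, node_id = nodes,
                      metric = c("ec", "cc"), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  base <- rnorm(nrow(grid))
  mt <- do.call(rbind, lapply(c("OXY", "PBO"), function(cond)
    data.frame(grid, condition = cond, value = base + rnorm(nrow(grid)),
               stringsAsFactors = FALSE)))
  if (!is.null(effects)) {
    gmap <- setNames(subjects$gender, subjects$subject_id)
    for (k in seq_len(nrow(effects))) {
      sel <- mt$condition == "OXY" &
        mt$node_id == effects$node_id[k] &
        mt$metric == effects$metric[k] &
        gmap[mt$subject_id] == effects$gender[k]
      mt$value[sel] <- mt$value[sel] + effects$d[k] * sqrt(2)
    }
  }
  list(metric_table = mt, subjects = subjects)
}
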