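test_that("cohort structure, randomization balance and determinism", {
  cfg <- small_config(n_female = 6, n_male = 8, n_time = 40)
  ch1 <- simulate_cohort(cfg, seed = 11)
  ch2 <- simulate_cohort(cfg, seed = 11)
  ch3 <- simulate_cohort(cfg, seed = 12)
  expect_identical(ch1$subjects, ch2$subjects)
  expect_identical(ch1$series, ch2$series)
  expect_false(identical(ch1$series[[1]]$signal, ch3$series[[1]]$signal))

  subj <- ch1$subjects
  expect_equal(nrow(subj), 14)
  expect_equal(sum(subj$gender == "female"), 6)
  expect_equal(length(ch1$series), 2 * nrow(subj))
  # each subject sees each condition exactly once
  expect_true(all(subj$visit1_condition != subj$visit2_condition))
  # balanced block randomization within gender (blocks of 2 or 4)
  for (g in c("female", "male")) {
    tab <- table(subj$treatment_order[subj$gender == g])
    expect_lte(abs(diff(range(tab))), 2)
  }
  # CTQ items: 25 per subject on a 1-5 scale, summing to the total
  items <- subj$ctq_items
  expect_true(all(vapply(items, length, 1L) == 25))
  expect_true(all(unlist(items) >= 1 & unlist(items) <= 5))
  expect_equal(vapply(items, sum, 1), as.numeric(subj$ctq_total))
  expect_true(all(subj$ctq_total >= 25 & subj$ctq_total <= 125))
})

test_that("corrupt mask honors the configured rate", {
  cfg0 <- small_config(n_female = 2, n_male = 2, n_time = 50,
                       corrupt_rate = c(female = 0, male = 0),
                       effects = no_effects())
  ch0 <- simulate_cohort(cfg0, seed = 5)
  expect_false(any(unlist(lapply(ch0$series, `[[`, "corrupt_mask"))))

  cfg <- small_config(n_female = 6, n_male = 6, n_time = 180,
                      effects = no_effects())
  ch <- simulate_cohort(cfg, seed = 21)
  gmap <- setNames(ch$subjects$gender, ch$subjects$subject_id)
  for (g in c("female", "male")) {
    masks <- unlist(lapply(ch$series[gmap[sub("_v[12]$", "",
                                              names(ch$series))] == g],
                           `[[`, "corrupt_mask"))
    expect_lt(abs(mean(masks) - cfg$corrupt_rate[[g]]), 0.03)
  }
})

test_that("time-series covariance matches the generating matrix", {
  base <- diag(4)
  base[1, 2] <- base[2, 1] <- 0.5
  dimnames(base) <- list(paste0("v", 1:4), paste0("v", 1:4))
  cfg <- small_config(n_time = 10000, artifact_sd = 0,
                      effects = no_effects())
  ts <- simulate_timeseries(subject_stub(), 1, no_effects(), base, cfg,
                            seed = 3)
  implied <- cov2cor(base)[1, 2]
  expect_lt(abs(cor(ts$signal[1, ], ts$signal[2, ]) - implied), 0.05)
  expect_lt(max(abs(cor(t(ts$signal))[cbind(c(1, 3), c(3, 4))])), 0.05)

  # determinism and condition-independence under an empty effect spec
  s_oxy <- simulate_timeseries(subject_stub(first = "OXY"), 1, no_effects(),
                               base, cfg, seed = 9)
  s_pbo <- simulate_timeseries(subject_stub(first = "PBO"), 1, no_effects(),
                               base, cfg, seed = 9)
  expect_identical(s_oxy$signal, s_pbo$signal)
  expect_error(simulate_timeseries(subject_stub(), 1, no_effects(),
                                   matrix(c(1, 2, 2, 1), 2), cfg, seed = 1),
               "positive-definite")
})

test_that("planted treatment effects shift the generating covariance", {
  cfg <- small_config(n_time = 8000, artifact_sd = 0)
  eff <- cfg$effects
  base <- build_base_cov(cfg)
  ts_oxy <- simulate_timeseries(subject_stub(gender = "male"), 1, eff, base,
                                cfg, seed = 13)
  ts_pbo <- simulate_timeseries(subject_stub(gender = "male", first = "PBO"),
                                1, eff, base, cfg, seed = 13)
  blocks <- attr(base, "blocks")
  partners <- setdiff(names(blocks)[blocks == blocks["r_acc"]], "r_acc")
  rho_oxy <- mean(cor(t(ts_oxy$signal))["r_acc", partners])
  rho_pbo <- mean(cor(t(ts_pbo$signal))["r_acc", partners])
  expect_gt(rho_oxy - rho_pbo, 0.1)
})

test_that("plant_outcome creates the requested associations", {
  set.seed(31)
  n <- 2000
  subjects <- data.frame(
    subject_id = sprintf("P%04d", 1:n),
    gender = "male",
    ctq_total = round(pmin(pmax(rnorm(n, 45, 15), 25), 125)),
    years_use = round(rnorm(n, 20, 5), 1), stringsAsFactors = FALSE)
  subjects$ctq_items <- I(lapply(subjects$ctq_total,
                                 oxynet:::ctq_items_from_total))
  deltas <- do.call(rbind, lapply(c("na", "nb"), function(nd)
    data.frame(subject_id = subjects$subject_id, node_id = nd,
               metric = "ec", delta = rnorm(n), stringsAsFactors = FALSE)))

  # zero slope: outcome independent of deltas
  l0 <- data.frame(outcome = "YRSUSE", gender = "male", node_id = "na",
                   metric = "ec", slope = 0, stringsAsFactors = FALSE)
  s0 <- plant_outcome(subjects, deltas, l0, seed = 1)
  d_na <- deltas$delta[deltas$node_id == "na"]
  expect_lt(abs(cor(s0$years_use, d_na)), 0.1)

  # single link at true R2 = 0.5 (slope 1, noise 1): fitted R2 within 0.05
  l1 <- data.frame(outcome = "YRSUSE", gender = "male", node_id = "na",
                   metric = "ec", slope = 1, stringsAsFactors = FALSE)
  s1 <- plant_outcome(subjects, deltas, l1, seed = 2, noise_sd = 1)
  r2 <- summary(lm(s1$years_use ~ d_na))$r.squared
  expect_lt(abs(r2 - 0.5), 0.05)
  expect_lt(abs(attr(s1, "planted_r2")[["YRSUSE_male"]] - 0.5), 0.05)

  # two equal slopes on independent standardized deltas: near-equal weights
  l2 <- data.frame(outcome = "YRSUSE", gender = "male",
                   node_id = c("na", "nb"), metric = "ec", slope = 0.7,
                   stringsAsFactors = FALSE)
  s2 <- plant_outcome(subjects, deltas, l2, seed = 3)
  d_nb <- deltas$delta[deltas$node_id == "nb"]
  cf <- coef(lm(s2$years_use ~ d_na + d_nb))[-1]
  expect_lt(abs(abs(cf[1]) - abs(cf[2])) / mean(abs(cf)), 0.2)

  expect_error(plant_outcome(subjects, deltas,
                             data.frame(outcome = "CTQ", gender = "male",
                                        node_id = "zz", metric = "ec",
                                        slope = 1), seed = 4),
               "absent")
})

test_that("null cohort yields null node deltas downstream", {
  cfg <- small_config(n_female = 12, n_male = 12, n_time = 120,
                      effects = no_effects())
  run <- run_pipeline(cfg, seed = 41, verbose = FALSE)
  agg <- aggregate(delta ~ node_id + metric, run$deltas, function(d)
    abs(mean(d)) / (sd(d) / sqrt(length(d))))
  # per-cell null t-statistics: no systematic shift
  expect_lt(mean(agg$delta > 2), 0.15)
  expect_lt(max(agg$delta), 4)
})
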