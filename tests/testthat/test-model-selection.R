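test_that("outlier trimming removes gross outliers and nothing else", {
  set.seed(41)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  y[7] <- 1e6
  tm <- trim_outliers(X, y)
  expect_equal(tm$removed, 7L)
  expect_equal(length(tm$y), 19)
  # disabled: identity
  tm0 <- trim_outliers(X, y, enabled = FALSE)
  expect_identical(tm0$y, y)
  # clean Gaussian outcome: about the normal tail mass beyond 3 robust SD
  fr <- mean(sapply(1:5, function(s) {
    set.seed(s)
    yy <- rnorm(1000)
    length(trim_outliers(matrix(0, 1000, 1), yy)$removed) / 1000
  }))
  expect_lte(fr, 0.01)
  expect_error(trim_outliers(X[1:5, ], y[1:5]), "at least 10")
})

test_that("best subsets finds a noiseless planted predictor", {
  set.seed(42)
  X <- matrix(rnorm(60 * 6), 60, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  y <- 2 * X[, 3]
  fit <- best_subsets_fit(X, y, seed = 1)
  expect_equal(fit$selected_subset, "x3")
  expect_lt(fit$test_ase, 1e-12)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["x3"]), 2, tolerance = 1e-9)
  expect_equal(unname(fit$importance), 1)
})

test_that("selection equals exhaustive enumeration at small p", {
  set.seed(43)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- 0.8 * X[, 2] - 0.5 * X[, 5] + rnorm(n)
  tr <- sort(sample(n, 28)); te <- setdiff(1:n, tr)
  # oracle: lm over all 63 nonempty subsets
  best <- list(ase = Inf, S = NULL)
  for (k in 1:6) {
    for (ci in seq_len(ncol(combn(6, k)))) {
      S <- combn(6, k)[, ci]
      f <- lm(y[tr] ~ X[tr, S, drop = FALSE])
      pred <- cbind(1, X[te, S, drop = FALSE]) %*% coef(f)
      ase <- mean((y[te] - pred)^2)
      if (ase < best$ase) best <- list(ase = ase, S = S)
    }
  }
  fit <- best_subsets_fit(X, y, max_subset_size = 6, train_index = tr)
  expect_equal(sort(fit$selected_subset), sort(paste0("x", best$S)))
  expect_equal(fit$test_ase, best$ase, tolerance = 1e-10)
})

test_that("split sizes, preconditions and index partition", {
  set.seed(44)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- rnorm(100)
  fit <- best_subsets_fit(X, y, seed = 2)
  expect_equal(length(fit$train_index), 70)
  expect_equal(sort(c(fit$train_index, fit$test_index)), 1:100)
  expect_error(best_subsets_fit(X[1:8, ], y[1:8]), "at least 10")
  expect_error(best_subsets_fit(matrix(rnorm(30 * 22), 30), rnorm(30)),
               "21")
  expect_error(best_subsets_fit(X[1:10, ], y[1:10],
                                split_fraction = 0.9),
               "smaller than 3")
})

test_that("leave-one-out importance sums to 1 and splits evenly when it should", {
  set.seed(45)
  n <- 10000
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- resid(lm(x2 ~ x1))            # exactly orthogonal
  x1 <- scale(x1)[, 1]; x2 <- scale(x2)[, 1]
  y <- x1 + x2 + rnorm(n)
  fit <- lm(y ~ x1 + x2)
  imp <- loo_importance(fit)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  # oracle: equal RSS increments under orthogonality and equal coefficients
  expect_lt(abs(imp[["x1"]] - 0.5), 0.02)

  single <- lm(y ~ x1)
  expect_equal(loo_importance(single), c(x1 = 1))

  set.seed(46)
  Xr <- matrix(rnorm(50 * 4), 50, 4,
               dimnames = list(NULL, paste0("z", 1:4)))
  fr <- lm(y ~ ., data.frame(y = rnorm(50), Xr))
  expect_equal(sum(loo_importance(fr)), 1, tolerance = 1e-9)
  expect_true(all(loo_importance(fr) >= 0))
})

test_that("replicated selection accumulates importance correctly", {
  set.seed(47)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 2 * X[, 1]                      # noiseless: every replication picks x1
  sel <- replicate_selection(X, y, n_replications = 10, seed = 3)
  expect_equal(length(sel$replications), 10)
  expect_equal(unname(sel$cumulative_importance["x1"]), 10)
  expect_equal(unname(sum(sel$cumulative_importance)), 10)
  expect_equal(sel$final_predictors, "x1")
  expect_equal(sel$n_significant, 10)

  # cumulative importance always sums to the replication count
  y2 <- rnorm(n)
  sel2 <- replicate_selection(X, y2, n_replications = 7, seed = 4)
  expect_equal(unname(sum(sel2$cumulative_importance)), 7,
               tolerance = 1e-9)
})

test_that("selection is invariant to affine rescaling of a predictor", {
  set.seed(48)
  n <- 50
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X[, 2] + 0.5 * X[, 4] + rnorm(n, sd = 0.5)
  X2 <- X
  X2[, 2] <- X2[, 2] * 1000 + 5
  f1 <- best_subsets_fit(X, y, seed = 9)
  f2 <- best_subsets_fit(X2, y, seed = 9)
  expect_equal(f1$selected_subset, f2$selected_subset)
  expect_equal(f1$test_ase, f2$test_ase, tolerance = 1e-8)
  expect_equal(f1$importance, f2$importance, tolerance = 1e-8)
})

test_that("VIFs match the closed form and drive pruning", {
  set.seed(49)
  n <- 500
  # orthogonal predictors: VIF 1
  x1 <- scale(rnorm(n))[, 1]
  x2 <- scale(resid(lm(rnorm(n) ~ x1)))[, 1]
  expect_equal(unname(compute_vif(cbind(a = x1, b = x2))), c(1, 1),
               tolerance = 1e-12)

  # correlation 0.9: VIF = 1 / (1 - 0.81)
  z <- rnorm(n)
  x3 <- x1 * 0.9 + sqrt(1 - 0.81) * z
  X <- cbind(a = x1, b = x3)
  r <- cor(x1, x3)
  v <- compute_vif(X)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-10)

  # cross-check against car's implementation
  if (requireNamespace("car", quietly = TRUE)) {
    y <- rnorm(n)
    fit <- lm(y ~ a + b, data.frame(y = y, a = x1, b = x3))
    expect_equal(unname(v), unname(car::vif(fit)), tolerance = 1e-10)
  }

  # duplicated predictor: infinite VIF, one copy dropped by pruning
  Xd <- cbind(a = x1, b = x1, c = x2)
  y <- x1 + x2 + rnorm(n, sd = 0.3)
  fin <- finalize_with_vif(Xd, y)
  expect_equal(length(fin$dropped), 1)
  expect_true(fin$dropped %in% c("a", "b"))
  expect_true(all(fin$vif < 4))
  # orthogonal survivors
  expect_equal(sort(c(fin$predictors, fin$dropped)), c("a", "b", "c"))
})

test_that("planted outcome link dominates cumulative importance", {
  set.seed(50)
  n <- 93
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, c(paste0("node", 1:20), "head_motion")))
  # true R2 = 0.3: slope sqrt(0.3 / 0.7) on a standardized predictor
  y <- sqrt(0.3 / 0.7) * X[, 7] + rnorm(n)
  sel <- replicate_selection(X, y, seed = 5)
  expect_equal(names(which.max(sel$cumulative_importance)), "node7")
  expect_true("node7" %in% sel$final_predictors)
})
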