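# observed/predicted pair with an exact 1 - SSres/SStot determination
# coefficient: pred = mean + a*(obs - mean) with (1-a)^2 = 1 - r2
vectors_with_r2 <- function(r2, n) {
  obs <- seq(4, 8, length.out = n)
  list(obs = obs, pred = mean(obs) + (1 - sqrt(1 - r2)) * (obs - mean(obs)))
}

test_that("fit metrics reproduce the derived statistics of a QSAR table", {
  v <- vectors_with_r2(0.779, 28)
  m <- fit_metrics(v$obs, v$pred, p = 5)
  expect_equal(m$r2, 0.779, tolerance = 1e-12)
  expect_equal(m$r2_adj, 0.729, tolerance = 1e-3)
  expect_equal(m$f_stat, 15.508, tolerance = 5e-2)
  v2 <- vectors_with_r2(0.938, 28)
  m2 <- fit_metrics(v2$obs, v2$pred, p = 5)
  expect_equal(m2$r2_adj, 0.924, tolerance = 1e-3)
  # identity case
  m3 <- fit_metrics(v$obs, v$obs, p = 5)
  expect_equal(m3$r2, 1)
  expect_equal(m3$rmse, 0)
  expect_error(fit_metrics(rep(1, 10), rnorm(10), p = 2), "zero variance")
})

test_that("LOO Q2 equals the explicit refit-loop oracle", {
  s <- synth_qsar(8, 3, k_informative = 2, noise_sd = 0.3, seed = 2)
  got <- q2_loo(s$data)
  press_oracle <- loo_press_oracle(s$data$x, s$data$y)
  expect_equal(got$press, press_oracle, tolerance = 1e-10)
  # the generic fitter route agrees with the closed form
  got2 <- q2_loo(s$data, fitter = function(d, sub) fit_mlr(d, sub))
  expect_equal(got2$press, got$press, tolerance = 1e-10)
  # noiseless data: every deleted prediction is exact
  s0 <- synth_qsar(12, 3, k_informative = 2, noise_sd = 0, seed = 3)
  expect_equal(q2_loo(s0$data)$q2, 1, tolerance = 1e-10)
})

test_that("Q2_LOO never exceeds training R2 for OLS fits", {
  for (seed in 1:8) {
    s <- synth_qsar(20, 6, k_informative = 3,
                    noise_sd = 0.1 + 0.1 * seed, seed = seed)
    fit <- fit_mlr(s$data, s$true_subset)
    r2 <- r_squared(s$data$y, predict(fit))
    expect_lte(q2_loo(s$data, s$true_subset)$q2, r2)
  }
})

test_that("bootstrap Q2 is exact on noiseless data and tracks Q2_LOO", {
  s0 <- synth_qsar(15, 4, k_informative = 2, noise_sd = 0, seed = 5)
  b <- q2_bootstrap(s0$data, s0$true_subset, B = 50, seed = 1)
  expect_equal(b$q2_boot, 1, tolerance = 1e-10)
  s <- synth_qsar(28, 6, k_informative = 3, noise_sd = 0.3, seed = 7)
  q_loo <- q2_loo(s$data, s$true_subset)$q2
  q_boot <- q2_bootstrap(s$data, s$true_subset, B = 200, seed = 1)$q2_boot
  expect_lt(abs(q_boot - q_loo), 0.1)
  # determinism under seed
  expect_identical(q_boot,
                   q2_bootstrap(s$data, s$true_subset, B = 200,
                                seed = 1)$q2_boot)
})

test_that("Y-randomization destroys a genuine structure-activity signal", {
  s <- synth_qsar(28, 6, k_informative = 3, noise_sd = 0.2, seed = 11)
  yr <- y_randomization(s$data, s$true_subset, n_iter = 10, seed = 4)
  expect_equal(nrow(yr), 10)
  fit <- fit_mlr(s$data, s$true_subset)
  r2_real <- r_squared(s$data$y, predict(fit))
  expect_lt(max(yr$r2), r2_real)
  expect_identical(yr, y_randomization(s$data, s$true_subset,
                                       n_iter = 10, seed = 4))
  # shuffling the activity drives Q2 to or below zero on strong signal
  set.seed(9)
  shuffled <- qsar_data(s$data$x, y = sample(s$data$y))
  expect_lt(q2_loo(shuffled, s$true_subset)$q2, 0.2)
})

test_that("concordance correlation follows Lin's closed form", {
  obs <- c(4.1, 5.2, 6.0, 6.8, 7.5)
  expect_equal(ccc(obs, obs), 1)
  # constant shift with unit (biased) variance: CCC = 2/3, Pearson r = 1
  o2 <- c(4, 6)                       # biased variance exactly 1
  expect_equal(ccc(o2, o2 + 1), 2 / 3, tolerance = 1e-12)
  expect_equal(cor(o2, o2 + 1), 1)
  # perfect discordance: mirrored about the mean
  expect_equal(ccc(obs, 2 * mean(obs) - obs), -1, tolerance = 1e-12)
  # |CCC| <= |r| on random vectors
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10, a)
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  expect_error(ccc(rep(1, 4), rep(2, 4)), "constant")
})

test_that("rm2 matches a step-by-step evaluation of Roy's formula", {
  obs <- c(4.2, 5.0, 5.9, 6.4, 7.3)
  pred <- c(4.5, 4.9, 6.2, 6.1, 7.0)
  r2 <- cor(obs, pred)^2
  k <- sum(obs * pred) / sum(obs^2)             # origin slope, pred on obs
  r0_2 <- 1 - sum((pred - k * obs)^2) / sum((pred - mean(pred))^2)
  expect_equal(rm2(obs, pred), r2 * (1 - sqrt(max(r2 - r0_2, 0))),
               tolerance = 1e-12)
  expect_equal(rm2(obs, obs), 1, tolerance = 1e-12)
  expect_error(rm2(obs, rep(5, 5)), "degenerate")
})

test_that("Golbraikh-Tropsha conditions evaluate the printed thresholds", {
  obs <- c(4.2, 5.1, 6.3, 7.0, 7.8)
  gt <- golbraikh_tropsha(obs, obs, q2_loo = 0.9)
  expect_true(gt$all_passed)
  expect_equal(gt$k, 1); expect_equal(gt$k_prime, 1)
  expect_equal(gt$r0_2, 1); expect_equal(gt$r0_prime_2, 1)

  # k and r0^2 match independent origin-regression fits (lm with no intercept)
  set.seed(31)
  pred <- obs + rnorm(5, sd = 0.3)
  gt2 <- golbraikh_tropsha(obs, pred, q2_loo = 0.674)
  expect_equal(gt2$k, unname(coef(lm(obs ~ 0 + pred))), tolerance = 1e-12)
  expect_equal(gt2$k_prime, unname(coef(lm(pred ~ 0 + obs))), tolerance = 1e-12)
  r0_oracle <- 1 - sum(residuals(lm(obs ~ 0 + pred))^2) /
    sum((obs - mean(obs))^2)
  expect_equal(gt2$r0_2, r0_oracle, tolerance = 1e-12)

  # conditions I and II apply the 0.5 / 0.6 thresholds to supplied values
  gt3 <- golbraikh_tropsha(obs, pred, q2_loo = 0.674, r2_test = 0.823)
  expect_true(gt3$conditions[["condition_1"]])
  expect_true(gt3$conditions[["condition_2"]])
  expect_false(golbraikh_tropsha(obs, pred, q2_loo = 0.4)$conditions[[1]])
})

test_that("VIF computation routes agree and respect the >= 1 bound", {
  expect_equal(unname(vif_from_correlation(diag(3))), rep(1, 3))
  r2x2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(unname(vif_from_correlation(r2x2)), rep(1.5625, 2),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("D", 1:4)))
    x[, 4] <- x[, 1] + rnorm(40, sd = 1.5)
    R <- cor(x)
    v <- vif_from_correlation(R)
    # independent route: per-descriptor regression on the others
    v_reg <- sapply(1:4, function(j) {
      r2_j <- summary(lm(x[, j] ~ x[, -j]))$r.squared
      1 / (1 - r2_j)
    })
    expect_equal(unname(v), v_reg, tolerance = 1e-9)
    expect_true(all(v >= 1))
  }
  # symmetrization of a printed lower triangle
  R <- diag(3); R[lower.tri(R)] <- c(0.3, 0.2, 0.1)
  expect_equal(vif_from_correlation(R),
               vif_from_correlation(R + t(R) - diag(3)), tolerance = 1e-12)
  expect_error(vif_from_correlation(matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("validate_model assembles the full battery for both model types", {
  s <- synth_qsar(35, 12, k_informative = 4, noise_sd = 0.25, seed = 51)
  tree <- cluster_compounds(s$data)
  sp <- make_split(tree, s$data, seed = 3)
  rows <- gaqsar:::split_rows(sp, s$data)
  train <- s$data[rows$train, ]; test <- s$data[rows$test, ]
  fit <- fit_mlr(train, s$true_subset)
  rep <- validate_model(fit, train, test, n_boot = 100, n_yrand = 5, seed = 2)
  expect_s3_class(rep, "qsar_validation")
  expect_equal(nrow(rep$y_randomization), 5)
  expect_length(rep$vif, 4)
  expect_s3_class(rep$gt, "gt_report")
  expect_true(all(c("r2", "rmse", "ccc", "rm2") %in% names(rep$test)))
  svr <- fit_svr(train, s$true_subset, C = 10, epsilon = 0.05, gamma = 1)
  rep2 <- validate_model(svr, train, test, n_boot = 30, n_yrand = 3, seed = 2)
  expect_null(rep2$vif)
  expect_true(is.finite(rep2$q2_loo))
})
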