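test_that("leverage domain reproduces hat-matrix identities", {
  s <- synth_qsar(28, 10, k_informative = 5, noise_sd = 0.3, seed = 61)
  fit <- fit_mlr(s$data, s$true_subset)
  ad <- leverage_domain(fit)
  # h* = 3 p'/n with p' = 6 parameters, n = 28
  expect_equal(ad$h_star, 3 * 6 / 28, tolerance = 1e-12)
  tr <- ad$compounds[ad$compounds$set == "train", ]
  # trace identity: mean training leverage = p'/n, sum = p'
  expect_equal(sum(tr$leverage), 6, tolerance = 1e-9)
  expect_true(all(tr$leverage > 0 & tr$leverage <= 1))
  # flags consistent with thresholds
  expect_identical(tr$outside_leverage, tr$leverage > ad$h_star)
  expect_identical(tr$outside_residual, abs(tr$std_residual) > 3)
  # well-conditioned synth training set: few leverage exceedances
  expect_lte(mean(tr$outside_leverage), 0.10)
})

test_that("query at the training centroid has minimal leverage 1/n", {
  s <- synth_qsar(25, 8, k_informative = 3, seed = 62)
  fit <- fit_mlr(s$data, s$true_subset)
  centroid <- matrix(colMeans(fit$x_train), 1,
                     dimnames = list("centroid", colnames(fit$x_train)))
  ad <- leverage_domain(fit, query = centroid)
  h_q <- ad$compounds$leverage[ad$compounds$set == "query"]
  expect_equal(h_q, 1 / 25, tolerance = 1e-10)
  expect_true(is.na(ad$compounds$std_residual[ad$compounds$set == "query"]))
})

test_that("standardized residuals use the training residual SD throughout", {
  s <- synth_qsar(30, 8, k_informative = 3, noise_sd = 0.4, seed = 63)
  train <- s$data[1:24, ]; test <- s$data[25:30, ]
  fit <- fit_mlr(train, s$true_subset)
  ad <- leverage_domain(fit, query = test)
  qr_rows <- ad$compounds[ad$compounds$set == "query", ]
  expect_equal(qr_rows$std_residual,
               unname((test$y - predict(fit, test)) / fit$sigma),
               tolerance = 1e-12)
})

test_that("Euclidean AD anchors training scores exactly to [0, 1]", {
  s <- synth_qsar(20, 6, k_informative = 3, seed = 64)
  ad <- euclidean_domain(s$data)
  sc <- ad$compounds$score
  expect_equal(min(sc), 0, tolerance = 1e-12)
  expect_equal(max(sc), 1, tolerance = 1e-12)
  expect_false(any(ad$compounds$outside))
})

test_that("Euclidean AD flags distant queries and keeps duplicates inside", {
  s <- synth_qsar(25, 5, k_informative = 3, seed = 65)
  dup <- s$data$x[3, , drop = FALSE]          # copy of a training compound
  rownames(dup) <- "copy"
  far <- matrix(colMeans(s$data$x) + 10 * apply(s$data$x, 2, sd), 1,
                dimnames = list("far", colnames(s$data$x)))
  ad <- euclidean_domain(s$data, query = rbind(dup, far))
  qr_rows <- ad$compounds[ad$compounds$set == "query", ]
  expect_false(qr_rows$outside[qr_rows$compound_id == "copy"])
  expect_gt(qr_rows$score[qr_rows$compound_id == "far"], 1)
  expect_true(qr_rows$outside[qr_rows$compound_id == "far"])
  # direct distance computation agrees for the far query
  xs <- scale(s$data$x)
  fq <- (far - attr(xs, "scaled:center")) / attr(xs, "scaled:scale")
  d_far <- mean(sqrt(rowSums(sweep(xs, 2, fq)^2)))
  expect_equal(qr_rows$mean_distance[qr_rows$compound_id == "far"], d_far,
               tolerance = 1e-10)
})

test_that("Euclidean scores are invariant to sign flips and column order", {
  # orthogonal transforms that commute with autoscaling: permutations and
  # axis reflections of the descriptor space
  s <- synth_qsar(18, 6, k_informative = 3, seed = 66)
  base <- euclidean_domain(s$data)$compounds$score
  set.seed(1)
  x2 <- s$data$x[, sample(6)] %*% diag(c(-1, 1, -1, 1, 1, -1))
  colnames(x2) <- paste0("T", 1:6)
  flipped <- euclidean_domain(qsar_data(x2, s$data$y))$compounds$score
  expect_equal(flipped, base, tolerance = 1e-10)
})

test_that("degenerate AD inputs raise errors", {
  x1 <- matrix(rnorm(4), 1, 4, dimnames = list("a", paste0("D", 1:4)))
  expect_error(euclidean_domain(qsar_data(x1)), "at least 2")
  xsame <- matrix(1:4, 3, 4, byrow = TRUE,
                  dimnames = list(NULL, paste0("D", 1:4)))
  expect_error(euclidean_domain(qsar_data(xsame)), "degenerate")
})
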