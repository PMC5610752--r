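test_that("constant filter removes exactly the uninformative columns", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  x <- cbind(x, Z = 0)                       # all-zeros column
  d <- qsar_data(x, y = rnorm(20))
  red <- filter_constant(d)
  expect_identical(colnames(red$data$x), c("A", "B", "C"))   # order preserved
  expect_identical(red$log$removed_constant, "Z")
  expect_identical(red$log$removed_near_constant, character(0))

  # synth table: count matches a direct frequency scan
  s <- synth_qsar(40, 30, n_constant = 4, n_near_constant = 3, seed = 13)
  red2 <- filter_constant(s$data)
  expect_equal(red2$log$n_before - red2$log$n_after, 7)
  expect_setequal(red2$log$removed_constant, s$planted$constant)
  expect_setequal(red2$log$removed_near_constant, s$planted$near_constant)

  # threshold 1.0 keeps near-constant columns
  red3 <- filter_constant(s$data, near_constant_fraction = 1.0)
  expect_equal(red3$log$n_before - red3$log$n_after, 4)
  expect_identical(red3$log$removed_near_constant, character(0))
})

test_that("collinear filter keeps the member better correlated with activity", {
  set.seed(2)
  n <- 200
  y <- rnorm(n)
  A <- 0.6 * y + rnorm(n, sd = 0.8)
  B <- A + rnorm(n, sd = 0.15)   # near-copy of A, necessarily worse on y
  noise <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("N", 1:3)))
  d <- qsar_data(cbind(A = A, B = B, noise), y = y)
  stopifnot(abs(cor(A, B)) > 0.9, abs(cor(A, y)) > abs(cor(B, y)))
  red <- filter_collinear(d)
  expect_identical(red$log$collinear_pairs$dropped, "B")
  expect_identical(red$log$collinear_pairs$kept, "A")
  expect_true("A" %in% colnames(red$data$x))
  expect_false("B" %in% colnames(red$data$x))
})

test_that("planted collinear pairs are resolved against a brute-force oracle", {
  s <- synth_qsar(50, 40, n_collinear_pairs = 3, seed = 4)
  red <- filter_collinear(s$data)
  # oracle: direct pairwise correlation scan of the generated table
  cm <- cor(s$data$x)
  hits <- which(abs(cm) > 0.9 & upper.tri(cm), arr.ind = TRUE)
  expect_equal(nrow(red$log$collinear_pairs), nrow(hits))
  expect_equal(red$log$n_before - red$log$n_after, nrow(hits))
  ry <- abs(cor(s$data$x, s$data$y))
  for (q in seq_len(nrow(hits))) {
    pair <- colnames(cm)[hits[q, ]]
    worse <- pair[which.min(ry[pair, 1])]
    expect_true(worse %in% red$log$collinear_pairs$dropped)
  }
})

test_that("no removals below the cut, and survivors stay below it", {
  s <- synth_qsar(200, 20, k_informative = 3, seed = 6)
  red <- filter_collinear(s$data, r_cut = 0.999)
  expect_equal(red$log$n_after, 20)
  cm <- cor(s$data$x)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.999)   # oracle scan agrees

  # post-hoc: surviving pairwise |r| <= r_cut after filtering at 0.9
  s2 <- synth_qsar(60, 25, n_collinear_pairs = 4, seed = 8)
  red2 <- filter_collinear(s2$data, r_cut = 0.9)
  cm2 <- cor(red2$data$x)
  expect_lte(max(abs(cm2[upper.tri(cm2)])), 0.9)
})

test_that("both filters are idempotent and preserve column order", {
  s <- synth_qsar(45, 30, n_constant = 2, n_near_constant = 2,
                  n_collinear_pairs = 2, seed = 10)
  r1 <- filter_constant(s$data)
  r1b <- filter_constant(r1$data)
  expect_identical(r1b$data$x, r1$data$x)
  r2 <- filter_collinear(r1$data)
  r2b <- filter_collinear(r2$data)
  expect_identical(r2b$data$x, r2$data$x)
  expect_true(all(diff(match(colnames(r2$data$x),
                             colnames(s$data$x))) > 0))
})

test_that("preprocessing errors are raised on bad input", {
  s <- synth_qsar(20, 6, seed = 1)
  no_y <- qsar_data(s$data$x)
  expect_error(filter_collinear(no_y), "activity")
  d <- qsar_data(matrix(1, 10, 2, dimnames = list(NULL, c("A", "B"))),
                 y = rnorm(10))
  expect_error(filter_constant(d), "all descriptor columns")
  expect_error(filter_collinear(s$data, r_cut = 1.2), "r_cut")
})
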