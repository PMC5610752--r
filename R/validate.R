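#' Determination coefficient of observed vs predicted activities
#'
#' Two conventions are in use in QSAR reporting: \code{"ss"} (default for
#' fit statistics), \eqn{1 - SS_{res}/SS_{tot}}, and \code{"cor"}, the
#' squared Pearson correlation, usual for external test-set tables.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param method \code{"ss"} or \code{"cor"}.
#' @return a single numeric value.
#' @export
r_squared <- function(observed, predicted, method = c("ss", "cor")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (stats::var(observed) == 0)
    stop("undefined R2: observed values have zero variance")
  if (method == "ss")
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  else
    stats::cor(observed, predicted)^2
}

#' Fit statistics: R2, RMSE, F and adjusted R2
#'
#' The battery reported for a QSAR training or test set. \code{F} and
#' \code{R2_adj} are derived from R2 and the degrees of freedom:
#' \eqn{F = (R^2/p) / ((1-R^2)/(n-p-1))},
#' \eqn{R^2_{adj} = 1 - (1-R^2)(n-1)/(n-p-1)}.
#'
#' @inheritParams r_squared
#' @param p number of model descriptors (excluding the intercept).
#' @param method R2 convention, see \code{\link{r_squared}}.
#' @return list with \code{r2}, \code{rmse}, \code{f_stat}, \code{r2_adj},
#'   \code{n}, \code{p}.
#' @examples
#' fit_metrics(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8), p = 1)
#' @export
fit_metrics <- function(observed, predicted, p, method = c("ss", "cor")) {
  n <- length(observed)
  if (n <= p + 1) stop("need n > p + 1 for F and adjusted R2")
  r2 <- r_squared(observed, predicted, method)
  list(r2 = r2,
       rmse = sqrt(mean((observed - predicted)^2)),
       f_stat = (r2 / p) / ((1 - r2) / (n - p - 1)),
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       n = n, p = p)
}

#' Leave-one-out cross-validated Q2 and PRESS
#'
#' Each compound is deleted in turn, the model is refitted on the remainder
#' and the deleted compound predicted; \eqn{Q^2 = 1 - PRESS/SS_{tot}} with
#' the total sum of squares about the full-training mean. For the default
#' OLS model the n refits are evaluated through the exact hat-matrix
#' identity \eqn{e_{(i)} = e_i/(1-h_{ii})} (identical to explicit refits, n
#' times faster); any other model is refitted explicitly via \code{fitter}.
#'
#' @param data a \code{\link{qsar_data}} with activity (training rows).
#' @param subset descriptor names; default all columns.
#' @param fitter NULL for OLS, or a function \code{(data, subset)} returning
#'   a fitted object with a \code{predict(object, newdata)} method.
#' @return list with \code{q2} and \code{press}.
#' @examples
#' s <- synth_qsar(20, 8, k_informative = 3, seed = 1)
#' q2_loo(s$data, s$true_subset)
#' @export
q2_loo <- function(data, subset = NULL, fitter = NULL) {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("q2_loo requires activity")
  if (is.null(subset)) subset <- colnames(data$x)
  n <- nrow(data$x)
  if (n < length(subset) + 3) stop("too few compounds for LOO refits")
  y <- data$y
  if (is.null(fitter)) {
    m <- press_mlr(data$x[, subset, drop = FALSE], y)
    if (!is.finite(m$q2)) stop("singular fit during LOO")
    return(list(q2 = m$q2, press = m$press))
  }
  press <- 0
  for (i in seq_len(n)) {
    fit_i <- tryCatch(fitter(data[-i, ], subset),
                      error = function(e)
                        stop("LOO fold ", i, " failed: ", conditionMessage(e)))
    pred_i <- stats::predict(fit_i, data[i, ])
    press <- press + (y[i] - pred_i)^2
  }
  sst <- sum((y - mean(y))^2)
  list(q2 = 1 - press / sst, press = unname(press))
}

#' Bootstrap-validated Q2
#'
#' B seeded bootstrap resamples of the training compounds; the model is
#' fitted on each resample and evaluated on its out-of-bag compounds.
#' Q2_boot pools all out-of-bag errors:
#' \eqn{1 - \sum e^2_{oob} / \sum (y_{oob} - \bar y_{resample})^2}.
#' Resamples with no out-of-bag compound (or a singular refit) are redrawn.
#'
#' @inheritParams q2_loo
#' @param B number of bootstrap repetitions (the classical choice for small
#'   QSAR sets is 5000).
#' @param seed integer RNG seed.
#' @return list with \code{q2_boot}, \code{B} and \code{n_redrawn}.
#' @export
q2_bootstrap <- function(data, subset = NULL, B = 5000, seed = 1,
                         fitter = NULL) {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("q2_bootstrap requires activity")
  if (B < 1) stop("B must be >= 1")
  if (is.null(subset)) subset <- colnames(data$x)
  n <- nrow(data$x)
  y <- data$y
  x <- data$x[, subset, drop = FALSE]
  set.seed(as.integer(seed))
  num <- den <- 0
  redrawn <- 0L
  b <- 0L
  while (b < B) {
    if (redrawn > 100L * B)
      stop("bootstrap could not draw usable resamples (", redrawn,
           " redraws); check the model/fitter on resampled data")
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) == 0) { redrawn <- redrawn + 1L; next }
    pred <- if (is.null(fitter)) {
      X <- cbind(1, x[idx, , drop = FALSE])
      qr_x <- qr(X)
      if (qr_x$rank < ncol(X)) { redrawn <- redrawn + 1L; next }
      drop(cbind(1, x[oob, , drop = FALSE]) %*% qr.coef(qr_x, y[idx]))
    } else {
      fit_b <- tryCatch(fitter(data[idx, ], subset), error = function(e) NULL)
      if (is.null(fit_b)) { redrawn <- redrawn + 1L; next }
      stats::predict(fit_b, data[oob, ])
    }
    num <- num + sum((y[oob] - pred)^2)
    den <- den + sum((y[oob] - mean(y[idx]))^2)
    b <- b + 1L
  }
  list(q2_boot = 1 - num / den, B = B, n_redrawn = redrawn)
}

#' Y-randomization (response scrambling) test
#'
#' Refits the model after randomly permuting the activity vector and records
#' the training R2 and leave-one-out Q2 of each scrambled model. Low values
#' relative to the unscrambled model indicate the QSAR is not a chance
#' correlation.
#'
#' @inheritParams q2_loo
#' @param n_iter number of permutations (default 10).
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{iteration}, \code{r2}, \code{q2}.
#' @export
y_randomization <- function(data, subset = NULL, n_iter = 10, seed = 1) {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("y_randomization requires activity")
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(subset)) subset <- colnames(data$x)
  x <- data$x[, subset, drop = FALSE]
  n <- nrow(x)
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n_iter), function(i) {
    y_perm <- data$y[sample.int(n)]
    m <- press_mlr(x, y_perm)
    data.frame(iteration = i, r2 = m$r2, q2 = m$q2)
  })
  do.call(rbind, out)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of predictions with the 45-degree identity line:
#' \eqn{CCC = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with biased
#' (1/n) moments. Unlike Pearson's r it penalizes location and scale shifts.
#'
#' @inheritParams r_squared
#' @return a single numeric value in [-1, 1].
#' @examples
#' ccc(1:5, 1:5)          # 1
#' ccc(1:5, 1:5 + 1)      # < 1: constant shift penalized
#' @export
ccc <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("need two equal-length vectors of length >= 2")
  n <- length(observed)
  mx <- mean(observed); my <- mean(predicted)
  sx2 <- mean((observed - mx)^2)
  sy2 <- mean((predicted - my)^2)
  if (sx2 == 0 && sy2 == 0) stop("CCC undefined: both vectors constant")
  sxy <- mean((observed - mx) * (predicted - my))
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# least-squares line through the origin of `response` on `predictor`:
# slope k = sum(r*p)/sum(p^2); R0^2 = 1 - SSres/SStot about the response mean
origin_regression <- function(response, predictor) {
  k <- sum(response * predictor) / sum(predictor^2)
  r0_2 <- 1 - sum((response - k * predictor)^2) /
    sum((response - mean(response))^2)
  list(k = k, r0_2 = r0_2)
}

#' Roy's modified R2 (rm2) external-validation metric
#'
#' \eqn{rm^2 = r^2 (1 - \sqrt{r^2 - r_0^2})}, where \eqn{r^2} is the squared
#' Pearson correlation of observed and predicted activities and
#' \eqn{r_0^2} the determination coefficient of the least-squares line
#' through the origin. The default axis convention regresses predicted
#' (response) on observed (predictor); \code{axes = "obs_vs_pred"} swaps
#' them. The difference \eqn{r^2 - r_0^2} is floored at zero.
#'
#' @inheritParams r_squared
#' @param axes which variable is the response of the origin regression.
#' @return a single numeric value.
#' @export
rm2 <- function(observed, predicted,
                axes = c("pred_vs_obs", "obs_vs_pred")) {
  axes <- match.arg(axes)
  if (length(observed) != length(predicted) || length(observed) < 3)
    stop("need two equal-length vectors of length >= 3")
  if (stats::var(observed) == 0 || stats::var(predicted) == 0)
    stop("rm2 undefined: degenerate variance")
  r2 <- stats::cor(observed, predicted)^2
  og <- if (axes == "pred_vs_obs") origin_regression(predicted, observed)
        else origin_regression(observed, predicted)
  r2 * (1 - sqrt(max(r2 - og$r0_2, 0)))
}

#' Golbraikh-Tropsha external-predictivity criteria
#'
#' Evaluates the four classical acceptance conditions for a QSAR model on an
#' external test set: (I) \eqn{Q^2_{LOO} > 0.5}; (II) \eqn{R^2 > 0.6};
#' (III) \eqn{(R^2 - R_0^2)/R^2 < 0.1} with \eqn{0.85 < k < 1.15}, or the
#' primed variant; (IV) \eqn{|R_0^2 - R_0'^2| < 0.3}. Here \eqn{k} is the
#' slope of observed on predicted through the origin (\eqn{k'} the reverse),
#' \eqn{R_0^2} the origin-constrained determination coefficient of observed
#' on predicted and \eqn{R_0'^2} the reverse, and \eqn{R^2} the squared
#' correlation.
#'
#' @param observed_test,predicted_test test-set activities, length >= 3.
#' @param q2_loo leave-one-out Q2 of the training model (condition I).
#' @param r2_test optional externally supplied R2 for conditions II/III;
#'   default the squared correlation of the test vectors.
#' @return an object of class \code{gt_report}: all computed quantities,
#'   the four condition booleans and \code{all_passed}.
#' @examples
#' obs <- c(4.2, 5.1, 6.3, 7.0, 7.8); gt <- golbraikh_tropsha(obs, obs, 0.9)
#' gt$all_passed
#' @export
golbraikh_tropsha <- function(observed_test, predicted_test, q2_loo,
                              r2_test = NULL) {
  if (length(observed_test) != length(predicted_test) ||
      length(observed_test) < 3)
    stop("need test vectors of equal length >= 3")
  if (sum(predicted_test^2) == 0 || sum(observed_test^2) == 0)
    stop("zero denominator in origin regression")
  r2 <- if (is.null(r2_test)) stats::cor(observed_test, predicted_test)^2
        else r2_test
  obs_on_pred <- origin_regression(observed_test, predicted_test)
  pred_on_obs <- origin_regression(predicted_test, observed_test)
  k <- obs_on_pred$k; k_prime <- pred_on_obs$k
  r0_2 <- obs_on_pred$r0_2; r0_prime_2 <- pred_on_obs$r0_2
  rel <- (r2 - r0_2) / r2
  rel_prime <- (r2 - r0_prime_2) / r2
  cond <- c(
    condition_1 = q2_loo > 0.5,
    condition_2 = r2 > 0.6,
    condition_3 = (rel < 0.1 && k > 0.85 && k < 1.15) ||
      (rel_prime < 0.1 && k_prime > 0.85 && k_prime < 1.15),
    condition_4 = abs(r0_2 - r0_prime_2) < 0.3)
  structure(list(q2_loo = q2_loo, r2 = r2, k = k, k_prime = k_prime,
                 r0_2 = r0_2, r0_prime_2 = r0_prime_2,
                 rel_diff = rel, rel_diff_prime = rel_prime,
                 abs_r0_diff = abs(r0_2 - r0_prime_2),
                 conditions = cond, all_passed = all(cond)),
            class = "gt_report")
}

#' @export
print.gt_report <- function(x, ...) {
  ok <- function(b) if (b) "Passed" else "FAILED"
  cat("Golbraikh-Tropsha external validation\n")
  cat(sprintf("  Condition I   Q2 = %.3f (> 0.5)        %s\n",
              x$q2_loo, ok(x$conditions[1])))
  cat(sprintf("  Condition II  R2 = %.3f (> 0.6)        %s\n",
              x$r2, ok(x$conditions[2])))
  cat(sprintf(
    "  Condition III k = %.3f, k' = %.3f; (R2-R02)/R2 = %.3f, (R2-R0'2)/R2 = %.3f  %s\n",
    x$k, x$k_prime, x$rel_diff, x$rel_diff_prime, ok(x$conditions[3])))
  cat(sprintf("  Condition IV  |R02 - R0'2| = %.4f (< 0.3)  %s\n",
              x$abs_r0_diff, ok(x$conditions[4])))
  invisible(x)
}

#' Variance inflation factors from a correlation matrix
#'
#' \eqn{VIF_i = 1/(1 - R_i^2)}, where \eqn{R_i^2} is the determination
#' coefficient of descriptor i regressed on all the others — equivalently
#' the i-th diagonal element of the inverse correlation matrix. A printed
#' lower-triangle matrix (upper entries zero or NA) is symmetrized first.
#'
#' @param corr_matrix square correlation matrix (full symmetric, or lower
#'   triangle with zero/NA above the diagonal), unit diagonal.
#' @return named numeric vector of VIFs (all >= 1).
#' @examples
#' vif_from_correlation(diag(3))             # all 1
#' vif_from_correlation(matrix(c(1, .6, .6, 1), 2))   # 1.5625 each
#' @export
vif_from_correlation <- function(corr_matrix) {
  R <- as.matrix(corr_matrix)
  if (nrow(R) != ncol(R)) stop("correlation matrix must be square")
  up <- R[upper.tri(R)]
  if (all(is.na(up) | up == 0) && any(R[lower.tri(R)] != 0, na.rm = TRUE)) {
    R[upper.tri(R)] <- 0
    R <- R + t(R) - diag(diag(R))
  }
  if (max(abs(R - t(R))) > 1e-8) stop("matrix is not symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) stop("diagonal must be 1")
  ch <- tryCatch(chol(R), error = function(e)
    stop("correlation matrix is singular or not positive definite"))
  v <- diag(chol2inv(ch))
  names(v) <- rownames(R)
  v
}

#' Variance inflation factors of a fitted MLR's descriptors
#'
#' @param fit a \code{qsar_mlr} fit.
#' @return named VIF vector computed from the training-set descriptor
#'   correlations.
#' @export
vif <- function(fit) {
  stopifnot(inherits(fit, "qsar_mlr"))
  vif_from_correlation(stats::cor(fit$x_train))
}

#' Full validation report for a fitted QSAR model
#'
#' Assembles the complete statistics battery for a \code{qsar_mlr} or
#' \code{qsar_svr} fit: training R2 / RMSE / F / adjusted R2 / CCC,
#' leave-one-out Q2 and PRESS, bootstrap Q2, Y-randomization table
#' (MLR refits), and — when a test set is supplied — test R2 / RMSE / CCC /
#' rm2 and the Golbraikh-Tropsha conditions. VIFs are reported for MLR fits.
#'
#' @param fit a \code{qsar_mlr} or \code{qsar_svr}.
#' @param train training \code{\link{qsar_data}} (with activity).
#' @param test optional test \code{\link{qsar_data}} (with activity).
#' @param n_boot bootstrap repetitions (default 5000).
#' @param n_yrand Y-randomization permutations (default 10).
#' @param seed integer seed for bootstrap and permutations.
#' @return an object of class \code{qsar_validation}.
#' @export
validate_model <- function(fit, train, test = NULL, n_boot = 5000,
                           n_yrand = 10, seed = 1) {
  stopifnot(inherits(fit, "qsar_mlr") || inherits(fit, "qsar_svr"))
  subset <- fit$descriptor_names
  p <- length(subset)
  is_svr <- inherits(fit, "qsar_svr")
  fitter <- if (is_svr)
    function(d, s) fit_svr(d, s, C = fit$C, epsilon = fit$epsilon,
                           gamma = fit$gamma) else NULL
  pred_tr <- stats::predict(fit, train)
  tr <- fit_metrics(train$y, pred_tr, p = p)
  loo <- q2_loo(train, subset, fitter = fitter)
  boot <- q2_bootstrap(train, subset, B = n_boot, seed = seed,
                       fitter = fitter)
  yr <- y_randomization(train, subset, n_iter = n_yrand, seed = seed)
  out <- list(
    model = class(fit)[1], descriptors = subset,
    r2 = tr$r2, rmse = tr$rmse, f_stat = tr$f_stat, r2_adj = tr$r2_adj,
    ccc_train = ccc(train$y, pred_tr),
    q2_loo = loo$q2, press = loo$press, q2_boot = boot$q2_boot,
    n_boot = n_boot, y_randomization = yr,
    vif = if (inherits(fit, "qsar_mlr")) vif(fit) else NULL,
    seed = as.integer(seed))
  if (!is.null(test)) {
    pred_te <- stats::predict(fit, test)
    out$test <- list(
      r2 = r_squared(test$y, pred_te, "cor"),
      rmse = sqrt(mean((test$y - pred_te)^2)),
      ccc = ccc(test$y, pred_te),
      rm2 = rm2(test$y, pred_te))
    out$gt <- golbraikh_tropsha(test$y, pred_te, q2_loo = loo$q2)
  }
  structure(out, class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat("Validation report (", x$model, ", ", length(x$descriptors),
      " descriptors)\n", sep = "")
  cat(sprintf(
    "  Training: R2 = %.3f  RMSE = %.3f  F = %.3f  R2_adj = %.3f  CCC = %.4f\n",
    x$r2, x$rmse, x$f_stat, x$r2_adj, x$ccc_train))
  cat(sprintf("  Internal: Q2_LOO = %.3f  PRESS = %.3f  Q2_BOOT = %.3f (B = %d)\n",
              x$q2_loo, x$press, x$q2_boot, x$n_boot))
  cat(sprintf("  Y-randomization (%d shuffles): max R2 = %.3f, max Q2 = %.3f\n",
              nrow(x$y_randomization), max(x$y_randomization$r2),
              max(x$y_randomization$q2)))
  if (!is.null(x$vif))
    cat("  VIF:", paste(sprintf("%s = %.3f", names(x$vif), x$vif),
                        collapse = ", "), "\n")
  if (!is.null(x$test)) {
    cat(sprintf(
      "  Test:     R2 = %.3f  RMSE = %.3f  CCC = %.4f  rm2 = %.3f\n",
      x$test$r2, x$test$rmse, x$test$ccc, x$test$rm2))
    print(x$gt)
  }
  invisible(x)
}
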