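# --- epsilon-SVR dual solver -------------------------------------------------
#
# Solves the standard eps-SVR dual
#   min 1/2 (a-a*)' K (a-a*) + eps * sum(a+a*) - y'(a-a*)
#   s.t. sum(a-a*) = 0,  0 <= a, a* <= C
# by sequential minimal optimization with maximal-violating-pair selection
# (the LIBSVM working-set rule). The 2n-variable QP is never materialized:
# block structure reduces every quantity to the n x n kernel matrix.
smo_svr <- function(K, y, C, epsilon, tol = 1e-6, max_iter = 100000L) {
  n <- length(y)
  sigma <- rep(c(1, -1), each = n)      # +1 for alpha, -1 for alpha*
  idx <- rep(seq_len(n), 2L)
  z <- numeric(2L * n)
  G <- c(epsilon - y, epsilon + y)      # gradient at z = 0
  Kd <- diag(K)
  m <- M <- NA_real_
  for (it in seq_len(max_iter)) {
    Fv <- -sigma * G
    in_up <- (sigma == 1 & z < C) | (sigma == -1 & z > 0)
    in_lo <- (sigma == 1 & z > 0) | (sigma == -1 & z < C)
    ui <- which(in_up); li <- which(in_lo)
    i <- ui[which.max(Fv[ui])]
    m <- Fv[i]
    M <- min(Fv[li])
    if (m - M < tol) break
    # second-order selection of j: maximal decrease of the two-variable
    # subproblem objective among violating lower-set candidates
    cand <- li[Fv[li] < m]
    aa <- pmax(Kd[idx[i]] + Kd[idx[cand]] - 2 * K[idx[i], idx[cand]], 1e-12)
    j <- cand[which.min(-(m - Fv[cand])^2 / aa)]
    a2 <- max(Kd[idx[i]] + Kd[idx[j]] - 2 * K[idx[i], idx[j]], 1e-12)
    d <- (m - Fv[j]) / a2
    d <- min(d,
             if (sigma[i] == 1) C - z[i] else z[i],
             if (sigma[j] == 1) z[j] else C - z[j])
    z[i] <- z[i] + sigma[i] * d
    z[j] <- z[j] - sigma[j] * d
    G <- G + sigma * (K[, idx[i]] - K[, idx[j]]) * d
  }
  list(beta = z[seq_len(n)] - z[n + seq_len(n)],
       b = (m + M) / 2, iterations = it, gap = m - M)
}

rbf_kernel <- function(a, b = a, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Fit an RBF epsilon-SVR QSAR model
#'
#' Support vector regression with a radial basis function kernel and
#' epsilon-insensitive loss. Descriptors and activity are autoscaled on the
#' training set (the RBF kernel needs commensurate scales); predictions are
#' back-transformed to pIC50. The dual quadratic program is solved by an
#' in-package SMO routine.
#'
#' @param data a \code{\link{qsar_data}} with activity (training rows).
#' @param subset descriptor names to use; default all columns.
#' @param C regularization (margin/error trade-off), > 0.
#' @param epsilon insensitivity-tube half width on the autoscaled activity,
#'   >= 0.
#' @param gamma RBF kernel width, > 0.
#' @return an object of class \code{qsar_svr}: dual coefficients
#'   \code{beta}, bias \code{b}, hyperparameters, training scaling constants
#'   and fitted values.
#' @seealso \code{\link{tune_svr}} for the leave-one-out grid search.
#' @export
fit_svr <- function(data, subset = NULL, C = 50, epsilon = 0.01, gamma = 5) {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("fit_svr requires activity")
  if (C <= 0 || epsilon < 0 || gamma <= 0)
    stop("require C > 0, epsilon >= 0, gamma > 0")
  if (is.null(subset)) subset <- colnames(data$x)
  x <- data$x[, subset, drop = FALSE]
  sx <- autoscale(x)
  y_center <- mean(data$y)
  y_scale <- stats::sd(data$y)
  if (y_scale == 0) y_scale <- 1
  ys <- (data$y - y_center) / y_scale
  K <- rbf_kernel(sx$x, gamma = gamma)
  sol <- smo_svr(K, ys, C = C, epsilon = epsilon)
  fitted_s <- drop(K %*% sol$beta) + sol$b
  obj <- structure(list(
    descriptor_names = subset,
    C = C, epsilon = epsilon, gamma = gamma,
    beta = sol$beta, b = sol$b,
    n_support = sum(abs(sol$beta) > 1e-8),
    x_train_scaled = sx$x,
    x_center = sx$center, x_scale = sx$scale,
    y_center = y_center, y_scale = y_scale,
    fitted = fitted_s * y_scale + y_center,
    y_train = data$y,
    n_train = nrow(x),
    iterations = sol$iterations
  ), class = "qsar_svr")
  obj$residuals <- data$y - obj$fitted
  obj
}

#' Predict pIC50 from a fitted SVR model
#'
#' @param object a \code{qsar_svr} fit.
#' @param newdata a \code{\link{qsar_data}} or matrix with the model's
#'   descriptor columns; default the training data. Queries are autoscaled
#'   with the training-set constants.
#' @param ... ignored.
#' @return numeric vector of predicted pIC50 values.
#' @export
predict.qsar_svr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- if (inherits(newdata, "qsar_data")) newdata$x else as.matrix(newdata)
  miss <- setdiff(object$descriptor_names, colnames(x))
  if (length(miss))
    stop("newdata lacks descriptors: ", paste(miss, collapse = ", "))
  x <- x[, object$descriptor_names, drop = FALSE]
  xs <- autoscale(x, object$x_center, object$x_scale)$x
  Kq <- rbf_kernel(xs, object$x_train_scaled, gamma = object$gamma)
  fs <- drop(Kq %*% object$beta) + object$b
  fs * object$y_scale + object$y_center
}

#' @export
residuals.qsar_svr <- function(object, ...) object$residuals

#' @export
print.qsar_svr <- function(x, ...) {
  cat("RBF epsilon-SVR QSAR model (", x$n_train, " training compounds, ",
      length(x$descriptor_names), " descriptors)\n", sep = "")
  cat("  C = ", x$C, ", epsilon = ", x$epsilon, ", gamma = ", x$gamma,
      ";  support vectors: ", x$n_support, "/", x$n_train, "\n", sep = "")
  invisible(x)
}

#' Default SVR hyperparameter grid
#'
#' The leave-one-out search grid used by \code{\link{tune_svr}}. It contains
#' the triple (C = 50, epsilon = 0.01, gamma = 5) commonly reported as
#' optimal for small autoscaled QSAR sets.
#'
#' @return data.frame with columns \code{C}, \code{gamma}, \code{epsilon}.
#' @export
default_svr_grid <- function() {
  expand.grid(C = c(1, 10, 50, 100), gamma = c(0.1, 1, 5, 10),
              epsilon = c(0.001, 0.01, 0.1), KEEP.OUT.ATTRS = FALSE)
}

#' Tune an RBF epsilon-SVR by leave-one-out RMSE and refit
#'
#' For every candidate (C, gamma, epsilon) triple the model is refitted n
#' times on n-1 training compounds and the root-mean-square error of the
#' deleted predictions (on the pIC50 scale) is recorded; the minimizing
#' triple is refitted on the full training set. Ties are broken toward the
#' smallest C, then smallest gamma, then smallest epsilon. Autoscaling
#' constants are taken from the full training set.
#'
#' @inheritParams fit_svr
#' @param grid data.frame of candidate hyperparameters with columns
#'   \code{C}, \code{gamma}, \code{epsilon}; default
#'   \code{\link{default_svr_grid}()}.
#' @return a \code{qsar_svr} fit carrying the search record in
#'   \code{$tuning} (the grid with a \code{loo_rmse} column).
#' @examples
#' s <- synth_qsar(20, 8, k_informative = 3, nonlinear = TRUE, seed = 2)
#' fit <- tune_svr(s$data, s$true_subset,
#'                 grid = data.frame(C = 50, gamma = 5, epsilon = 0.01))
#' fit$C
#' @export
tune_svr <- function(data, subset = NULL, grid = default_svr_grid()) {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("tune_svr requires activity")
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid")
  if (!all(c("C", "gamma", "epsilon") %in% names(grid)))
    stop("grid needs columns C, gamma, epsilon")
  if (is.null(subset)) subset <- colnames(data$x)
  x <- data$x[, subset, drop = FALSE]
  n <- nrow(x)
  sx <- autoscale(x)
  y_center <- mean(data$y); y_scale <- stats::sd(data$y)
  if (y_scale == 0) y_scale <- 1
  ys <- (data$y - y_center) / y_scale

  grid <- grid[order(grid$C, grid$gamma, grid$epsilon), , drop = FALSE]
  loo_rmse <- numeric(nrow(grid))
  for (g in unique(grid$gamma)) {
    K <- rbf_kernel(sx$x, gamma = g)
    rows <- which(grid$gamma == g)
    for (r in rows) {
      se <- 0
      for (i in seq_len(n)) {
        sol <- smo_svr(K[-i, -i, drop = FALSE], ys[-i],
                       C = grid$C[r], epsilon = grid$epsilon[r])
        pred_s <- sum(K[i, -i] * sol$beta) + sol$b
        se <- se + ((pred_s - ys[i]) * y_scale)^2
      }
      loo_rmse[r] <- sqrt(se / n)
    }
  }
  best <- which.min(loo_rmse)   # grid pre-sorted: first min = smallest C/gamma/epsilon
  fit <- fit_svr(data, subset, C = grid$C[best],
                 epsilon = grid$epsilon[best], gamma = grid$gamma[best])
  fit$tuning <- cbind(grid, loo_rmse = loo_rmse)
  fit
}
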