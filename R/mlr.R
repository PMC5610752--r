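#' Fit a multiple linear regression QSAR model
#'
#' Ordinary least squares of pIC50 on a descriptor subset, with coefficient
#' standard errors from the unbiased residual variance and the inverse
#' normal matrix. Descriptors enter on their raw scale, so coefficients read
#' directly as the familiar QSAR equation
#' \code{pIC50 = b0 (+/- se) + b1 (+/- se) X1 + ...}.
#'
#' @param data a \code{\link{qsar_data}} with activity (training rows).
#' @param subset character vector of descriptor names to use; default all
#'   columns of \code{data}.
#' @return an object of class \code{qsar_mlr}: coefficients, standard
#'   errors, fitted values, residuals, the training design, and bookkeeping
#'   (\code{n_train}, \code{df_residual}, \code{sigma}).
#' @examples
#' s <- synth_qsar(30, 20, noise_sd = 0.1, seed = 7)
#' fit <- fit_mlr(s$data, s$true_subset)
#' fit
#' coef(fit)
#' @export
fit_mlr <- function(data, subset = NULL) {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("fit_mlr requires activity")
  if (is.null(subset)) subset <- colnames(data$x)
  miss <- setdiff(subset, colnames(data$x))
  if (length(miss))
    stop("unknown descriptors: ", paste(miss, collapse = ", "))
  x <- data$x[, subset, drop = FALSE]
  y <- data$y
  n <- nrow(x); p <- length(subset)
  if (n <= p + 1)
    stop("need more training compounds than coefficients")
  X <- cbind("(Intercept)" = 1, x)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stop("singular fit: design matrix is rank deficient")
  coefs <- qr.coef(qr_x, y)
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  df <- n - p - 1L
  sigma2 <- sum(resid^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtX_inv))
  names(se) <- names(coefs)
  structure(list(
    descriptor_names = subset,
    coefficients = coefs,
    std_errors = se,
    fitted = fitted,
    residuals = resid,
    sigma = sqrt(sigma2),
    df_residual = df,
    n_train = n,
    x_train = x,
    y_train = y
  ), class = "qsar_mlr")
}

#' @export
coef.qsar_mlr <- function(object, ...) object$coefficients

#' @export
residuals.qsar_mlr <- function(object, ...) object$residuals

#' Predict pIC50 from a fitted MLR model
#'
#' @param object a \code{qsar_mlr} fit.
#' @param newdata a \code{\link{qsar_data}} or numeric matrix containing the
#'   model's descriptor columns; default the training data.
#' @param ... ignored.
#' @return numeric vector of predicted pIC50 values.
#' @export
predict.qsar_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- if (inherits(newdata, "qsar_data")) newdata$x else as.matrix(newdata)
  miss <- setdiff(object$descriptor_names, colnames(x))
  if (length(miss))
    stop("newdata lacks descriptors: ", paste(miss, collapse = ", "))
  x <- x[, object$descriptor_names, drop = FALSE]
  drop(cbind(1, x) %*% object$coefficients)
}

# "11.510 (+/- 1.329) + 249.056 (+/- 45.566) GATS6m - ..." equation layout
format_equation <- function(fit, digits = 3) {
  b <- fit$coefficients; se <- fit$std_errors
  term <- function(i) {
    val <- formatC(abs(b[i]), digits = digits, format = "f")
    sev <- formatC(se[i], digits = digits, format = "f")
    name <- if (i == 1) "" else paste0(" ", names(b)[i])
    paste0(val, " (± ", sev, ")", name)
  }
  out <- term(1)
  for (i in seq_along(b)[-1])
    out <- paste0(out, if (b[i] >= 0) " + " else " - ", term(i))
  paste0("pIC50 = ", out)
}

#' @export
print.qsar_mlr <- function(x, digits = 3, ...) {
  cat("Multiple linear regression QSAR model (", x$n_train,
      " training compounds, ", length(x$descriptor_names),
      " descriptors)\n\n", sep = "")
  cat(strwrap(format_equation(x, digits), width = 76, exdent = 8), sep = "\n")
  cat("\nResidual SD:", signif(x$sigma, 4), "on", x$df_residual,
      "degrees of freedom\n")
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  b <- object$coefficients; se <- object$std_errors
  tval <- b / se
  tab <- cbind(Estimate = b, `Std. Error` = se, `t value` = tval,
               `Pr(>|t|)` = 2 * stats::pt(abs(tval), object$df_residual,
                                          lower.tail = FALSE))
  y <- object$y_train
  r2 <- 1 - sum(object$residuals^2) / sum((y - mean(y))^2)
  structure(list(coefficients = tab, r_squared = r2,
                 sigma = object$sigma, df_residual = object$df_residual,
                 equation = format_equation(object)),
            class = "summary.qsar_mlr")
}

#' @export
print.summary.qsar_mlr <- function(x, ...) {
  cat(strwrap(x$equation, width = 76, exdent = 8), sep = "\n")
  cat("\n")
  stats::printCoefmat(x$coefficients)
  cat("\nR-squared:", signif(x$r_squared, 4),
      "  Residual SD:", signif(x$sigma, 4), "\n")
  invisible(x)
}

# OLS leave-one-out PRESS / Q2 by the exact hat-matrix identity
# e_(i) = e_i / (1 - h_ii); returns -Inf fitness on (near-)singular designs
press_mlr <- function(x, y) {
  X <- cbind(1, x)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) return(list(press = Inf, q2 = -Inf, r2 = -Inf))
  e <- qr.resid(qr_x, y)
  Q <- qr.Q(qr_x)
  h <- rowSums(Q^2)
  if (any(1 - h < 1e-10)) return(list(press = Inf, q2 = -Inf, r2 = -Inf))
  press <- sum((e / (1 - h))^2)
  sst <- sum((y - mean(y))^2)
  list(press = press, q2 = 1 - press / sst, r2 = 1 - sum(e^2) / sst)
}
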