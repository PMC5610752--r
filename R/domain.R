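#' Leverage (Williams plot) applicability domain
#'
#' Structural applicability domain of a linear QSAR model. The leverage of a
#' compound is \eqn{h_i = x_i' (X'X)^{-1} x_i} with \eqn{X} the training
#' design (intercept plus the model's descriptors); the warning threshold is
#' \eqn{h^* = 3 p' / n} with \eqn{p'} the number of model parameters
#' including the intercept. Residuals are standardized by the training
#' residual SD (for training and query compounds alike); compounds with
#' \eqn{h > h^*} or |standardized residual| > 3 fall outside the domain.
#'
#' @param fit a \code{qsar_mlr} fit.
#' @param query optional \code{\link{qsar_data}} of query/test compounds
#'   containing the model's descriptor columns (activity optional; without
#'   it query residuals are NA).
#' @return an object of class \code{qsar_leverage}: a per-compound
#'   data.frame (\code{compound_id}, \code{set}, \code{leverage},
#'   \code{std_residual}, \code{outside_leverage}, \code{outside_residual}),
#'   plus \code{h_star}, \code{sigma}, \code{p_prime}, \code{n_train}.
#' @examples
#' s <- synth_qsar(28, 10, k_informative = 3, seed = 1)
#' fit <- fit_mlr(s$data, s$true_subset)
#' ad <- leverage_domain(fit)
#' ad$h_star                      # 3 * 4 / 28
#' @export
leverage_domain <- function(fit, query = NULL) {
  stopifnot(inherits(fit, "qsar_mlr"))
  X <- cbind(1, fit$x_train)
  n <- nrow(X); p_prime <- ncol(X)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  h_train <- rowSums((X %*% XtX_inv) * X)
  h_star <- 3 * p_prime / n
  std_res_train <- fit$residuals / fit$sigma
  tab <- data.frame(compound_id = rownames(fit$x_train), set = "train",
                    leverage = unname(h_train),
                    std_residual = unname(std_res_train),
                    stringsAsFactors = FALSE)
  if (!is.null(query)) {
    xq <- if (inherits(query, "qsar_data"))
      query$x[, fit$descriptor_names, drop = FALSE]
    else as.matrix(query)[, fit$descriptor_names, drop = FALSE]
    Xq <- cbind(1, xq)
    h_q <- rowSums((Xq %*% XtX_inv) * Xq)
    res_q <- if (inherits(query, "qsar_data") && !is.null(query$y))
      (query$y - stats::predict(fit, query)) / fit$sigma else NA_real_
    tab <- rbind(tab, data.frame(
      compound_id = rownames(xq), set = "query",
      leverage = unname(h_q), std_residual = unname(res_q),
      stringsAsFactors = FALSE))
  }
  tab$outside_leverage <- tab$leverage > h_star
  tab$outside_residual <- !is.na(tab$std_residual) &
    abs(tab$std_residual) > 3
  structure(list(compounds = tab, h_star = h_star, sigma = fit$sigma,
                 p_prime = p_prime, n_train = n),
            class = "qsar_leverage")
}

#' @export
print.qsar_leverage <- function(x, ...) {
  n_out <- sum(x$compounds$outside_leverage | x$compounds$outside_residual)
  cat("Leverage applicability domain: h* = ", round(x$h_star, 4),
      " (p' = ", x$p_prime, ", n = ", x$n_train, "); ",
      n_out, " compound(s) outside\n", sep = "")
  invisible(x)
}

#' Williams plot of a leverage applicability domain
#'
#' Leverage versus standardized residual with the h* and +/-3 SD bounds.
#'
#' @param x a \code{qsar_leverage} object.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.qsar_leverage <- function(x, ...) {
  tab <- x$compounds
  graphics::plot(tab$leverage, tab$std_residual,
                 pch = ifelse(tab$set == "train", 19, 17),
                 col = ifelse(tab$set == "train", "steelblue", "firebrick"),
                 xlab = "Leverage (h)", ylab = "Standardized residual",
                 xlim = c(0, max(tab$leverage, x$h_star) * 1.1),
                 ylim = range(c(-3.5, 3.5, tab$std_residual), na.rm = TRUE),
                 main = "Williams plot", ...)
  graphics::abline(v = x$h_star, lty = 2)
  graphics::abline(h = c(-3, 3), lty = 3)
  graphics::legend("topright", legend = c("train", "query"),
                   pch = c(19, 17), col = c("steelblue", "firebrick"),
                   bty = "n")
  invisible(x)
}

#' Euclidean normalized-mean-distance applicability domain
#'
#' Diversity-based applicability domain. For each compound the mean
#' Euclidean distance to all training compounds is computed on descriptors
#' autoscaled by training statistics (self-distances excluded for training
#' compounds); training distances are then anchored to [0, 1] by
#' \eqn{(d - d_{min})/(d_{max} - d_{min})}, so the least diverse training
#' compound scores 0 and the most diverse scores 1. Query compounds are
#' scored with the same anchors; scores outside [0, 1] flag compounds
#' outside the domain.
#'
#' @param train training \code{\link{qsar_data}}.
#' @param query optional query \code{\link{qsar_data}} or matrix with the
#'   same descriptors.
#' @param subset descriptor names to use; default all training columns.
#' @return an object of class \code{qsar_euclid}: per-compound data.frame
#'   (\code{compound_id}, \code{set}, \code{mean_distance}, \code{score},
#'   \code{outside}), plus the anchors \code{d_min}, \code{d_max}.
#' @examples
#' s <- synth_qsar(20, 6, k_informative = 3, seed = 2)
#' ad <- euclidean_domain(s$data)
#' range(ad$compounds$score)      # exactly 0 and 1
#' @export
euclidean_domain <- function(train, query = NULL, subset = NULL) {
  stopifnot(inherits(train, "qsar_data"))
  if (nrow(train$x) < 2) stop("need at least 2 training compounds")
  if (is.null(subset)) subset <- colnames(train$x)
  xt <- train$x[, subset, drop = FALSE]
  sc <- autoscale(xt)
  n <- nrow(xt)
  dmat <- as.matrix(stats::dist(sc$x))
  d_train <- rowSums(dmat) / (n - 1)      # self-distance (0) excluded
  d_min <- min(d_train); d_max <- max(d_train)
  if (d_max == d_min)
    stop("degenerate spread: all training mean distances identical")
  tab <- data.frame(compound_id = rownames(xt), set = "train",
                    mean_distance = unname(d_train),
                    score = unname((d_train - d_min) / (d_max - d_min)),
                    stringsAsFactors = FALSE)
  if (!is.null(query)) {
    xq <- if (inherits(query, "qsar_data")) query$x else as.matrix(query)
    xq <- xq[, subset, drop = FALSE]
    xqs <- autoscale(xq, sc$center, sc$scale)$x
    # mean distance of each query to ALL training compounds
    cross <- sqrt(pmax(outer(rowSums(xqs^2), rowSums(sc$x^2), "+") -
                         2 * tcrossprod(xqs, sc$x), 0))
    d_q <- rowMeans(cross)
    tab <- rbind(tab, data.frame(
      compound_id = rownames(xq), set = "query",
      mean_distance = unname(d_q),
      score = unname((d_q - d_min) / (d_max - d_min)),
      stringsAsFactors = FALSE))
  }
  tab$outside <- tab$score < 0 | tab$score > 1
  structure(list(compounds = tab, d_min = d_min, d_max = d_max),
            class = "qsar_euclid")
}

#' @export
print.qsar_euclid <- function(x, ...) {
  cat("Euclidean applicability domain: ", sum(x$compounds$outside),
      " compound(s) outside [0, 1] of ", nrow(x$compounds), "\n", sep = "")
  invisible(x)
}

#' Plot Euclidean applicability-domain scores
#'
#' @param x a \code{qsar_euclid} object.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.qsar_euclid <- function(x, ...) {
  tab <- x$compounds
  graphics::plot(seq_len(nrow(tab)), tab$score,
                 pch = ifelse(tab$set == "train", 19, 17),
                 col = ifelse(tab$set == "train", "steelblue", "firebrick"),
                 xlab = "Compound", ylab = "Normalized mean distance score",
                 ylim = range(c(-0.1, 1.1, tab$score)),
                 main = "Euclidean applicability domain", ...)
  graphics::abline(h = c(0, 1), lty = 2)
  graphics::legend("topright", legend = c("train", "query"),
                   pch = c(19, 17), col = c("steelblue", "firebrick"),
                   bty = "n")
  invisible(x)
}
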