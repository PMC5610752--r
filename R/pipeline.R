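#' Run the full QSAR workflow end to end
#'
#' Orchestrates the complete modelling pipeline on a descriptor table:
#' descriptor reduction (constant and collinearity filters), hierarchical
#' cluster-based training/test split, genetic-algorithm descriptor
#' selection, MLR and leave-one-out tuned RBF epsilon-SVR fits on the same
#' selected subset (an apples-to-apples comparison), the full validation
#' battery for both models, and both applicability-domain analyses for the
#' linear model. Every stochastic stage is driven by \code{seed}; rerunning
#' with the same inputs reproduces the result exactly.
#'
#' @param data a \code{\link{qsar_data}} with activity, or NULL to simulate.
#' @param synth list of \code{\link{synth_qsar}} arguments used when
#'   \code{data} is NULL.
#' @param near_constant_fraction,r_cut preprocessing thresholds, see
#'   \code{\link{filter_constant}} and \code{\link{filter_collinear}}.
#' @param test_fraction,linkage split parameters, see
#'   \code{\link{make_split}} and \code{\link{cluster_compounds}}.
#' @param subset_size number of descriptors per model (default 5).
#' @param ga list of overrides for \code{\link{ga_select}} arguments
#'   (population_size, n_generations, n_runs, ...).
#' @param svr_grid SVR hyperparameter grid, see \code{\link{tune_svr}}.
#' @param n_boot,n_yrand validation parameters, see
#'   \code{\link{validate_model}}.
#' @param seed master integer seed for split, GA, bootstrap and
#'   Y-randomization.
#' @return an object of class \code{qsar_pipeline} collecting every stage
#'   artifact: \code{input}, \code{reduction}, \code{split}, \code{ga},
#'   \code{subset}, \code{mlr}, \code{svr}, \code{validation} (list with
#'   \code{mlr} and \code{svr} reports), \code{leverage_ad},
#'   \code{euclidean_ad}, and the configuration.
#' @examples
#' \donttest{
#' run <- qsar_pipeline(synth = list(n_compounds = 35, n_descriptors = 60,
#'                                   seed = 1),
#'                      ga = list(n_generations = 30), n_boot = 200,
#'                      seed = 1)
#' run
#' }
#' @export
qsar_pipeline <- function(data = NULL, synth = NULL,
                          near_constant_fraction = 0.95, r_cut = 0.9,
                          test_fraction = 0.2, linkage = "complete",
                          subset_size = 5, ga = list(),
                          svr_grid = default_svr_grid(),
                          n_boot = 5000, n_yrand = 10, seed = 1) {
  truth <- NULL
  if (is.null(data)) {
    if (is.null(synth))
      stop("supply either `data` or a `synth` configuration")
    synth_obj <- do.call(synth_qsar, synth)
    data <- synth_obj$data
    truth <- synth_obj
  }
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("pipeline requires activity")
  seed <- as.integer(seed)

  red <- reduce_descriptors(data, near_constant_fraction, r_cut)
  tree <- cluster_compounds(red$data, linkage)
  split <- make_split(tree, red$data, test_fraction, seed = seed)
  rows <- split_rows(split, red$data)
  train <- red$data[rows$train, ]
  test <- red$data[rows$test, ]

  ga_args <- utils::modifyList(
    list(data = train, subset_size = subset_size, seed = seed), ga)
  ga_res <- do.call(ga_select, ga_args)
  subset <- ga_best_subset(ga_res)

  mlr <- fit_mlr(train, subset)
  svr <- tune_svr(train, subset, grid = svr_grid)
  val_mlr <- validate_model(mlr, train, test, n_boot = n_boot,
                            n_yrand = n_yrand, seed = seed)
  val_svr <- validate_model(svr, train, test, n_boot = n_boot,
                            n_yrand = n_yrand, seed = seed)
  structure(list(
    input = data, truth = truth, reduction = red, tree = tree,
    split = split, ga = ga_res, subset = subset,
    mlr = mlr, svr = svr,
    validation = list(mlr = val_mlr, svr = val_svr),
    leverage_ad = leverage_domain(mlr, query = test),
    euclidean_ad = euclidean_domain(train, query = test, subset = subset),
    config = list(near_constant_fraction = near_constant_fraction,
                  r_cut = r_cut, test_fraction = test_fraction,
                  linkage = linkage, subset_size = subset_size,
                  n_boot = n_boot, n_yrand = n_yrand, seed = seed)
  ), class = "qsar_pipeline")
}

#' @export
print.qsar_pipeline <- function(x, ...) {
  cat("=== QSAR pipeline report (seed ", x$config$seed, ") ===\n\n", sep = "")
  cat("Descriptors: ", x$reduction$constant_log$n_before, " -> ",
      ncol(x$input$x) - length(x$reduction$constant_log$removed_constant) -
        length(x$reduction$constant_log$removed_near_constant), " -> ",
      x$reduction$collinear_log$n_after,
      " after constant and collinearity filters\n", sep = "")
  cat("Split: ", length(x$split$train_ids), " train / ",
      length(x$split$test_ids), " test (", x$split$linkage_method,
      " linkage, ", x$split$n_clusters, " clusters)\n\n", sep = "")
  cat("Selected descriptors (GA, ", x$ga$fitness_name, "): ",
      paste(x$subset, collapse = ", "), "\n\n", sep = "")
  cat(strwrap(format_equation(x$mlr), width = 76, exdent = 8), sep = "\n")
  cat("\nModel comparison (same descriptor subset):\n")
  vm <- x$validation$mlr; vs <- x$validation$svr
  row <- function(tag, v) {
    sprintf("  %-7s R2 = %.3f  RMSE = %.3f  F = %7.3f  CCC = %.4f  R2_adj = %.3f  Q2_LOO = %.3f",
            tag, v$r2, v$rmse, v$f_stat, v$ccc_train, v$r2_adj, v$q2_loo)
  }
  cat(row("GA-MLR", vm), "\n")
  cat(row("GA-SVM", vs), "\n")
  cat(sprintf("  Test    MLR: R2 = %.3f RMSE = %.3f rm2 = %.3f | SVM: R2 = %.3f RMSE = %.3f rm2 = %.3f\n",
              vm$test$r2, vm$test$rmse, vm$test$rm2,
              vs$test$r2, vs$test$rmse, vs$test$rm2))
  cat(sprintf("\nY-randomization (MLR, %d shuffles): max R2 = %.3f vs model R2 = %.3f\n",
              nrow(vm$y_randomization), max(vm$y_randomization$r2), vm$r2))
  print(vm$gt)
  print(x$leverage_ad)
  print(x$euclidean_ad)
  if (x$ga$n_runs > 1) {
    cat("\nAlternative GA models:\n")
    print(x$ga)
  }
  invisible(x)
}

#' Predicted-versus-observed plot for a pipeline run
#'
#' @param x a \code{qsar_pipeline}.
#' @param model \code{"mlr"} or \code{"svr"}.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.qsar_pipeline <- function(x, model = c("mlr", "svr"), ...) {
  model <- match.arg(model)
  fit <- x[[model]]
  rows <- split_rows(x$split, x$reduction$data)
  train <- x$reduction$data[rows$train, ]
  test <- x$reduction$data[rows$test, ]
  pt <- stats::predict(fit, train); pe <- stats::predict(fit, test)
  rng <- range(c(train$y, test$y, pt, pe))
  graphics::plot(train$y, pt, pch = 19, col = "steelblue",
                 xlim = rng, ylim = rng, xlab = "Experimental pIC50",
                 ylab = "Predicted pIC50",
                 main = paste0("GA-", toupper(model)), ...)
  graphics::points(test$y, pe, pch = 17, col = "firebrick")
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = c("train", "test"),
                   pch = c(19, 17), col = c("steelblue", "firebrick"),
                   bty = "n")
  invisible(x)
}
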