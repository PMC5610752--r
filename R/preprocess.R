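#' Remove constant and near-constant descriptors
#'
#' Drops descriptor columns that carry (almost) no information: columns with
#' zero variance, and columns whose most frequent value occurs in at least
#' \code{near_constant_fraction} of the compounds. The frequency rule is the
#' common Dragon-era definition of "near constant"; setting
#' \code{near_constant_fraction = 1} keeps it inactive so only exactly
#' constant columns are removed. Column order of the survivors is preserved.
#'
#' @param data a \code{\link{qsar_data}}.
#' @param near_constant_fraction mode-frequency threshold in (0, 1];
#'   default 0.95.
#' @return a list of class \code{qsar_reduction} with elements \code{data}
#'   (the reduced table) and \code{log} (names removed as constant /
#'   near-constant, and the before/after column counts).
#' @examples
#' s <- synth_qsar(35, 40, n_constant = 3, n_near_constant = 2, seed = 4)
#' red <- filter_constant(s$data)
#' red$log$n_before - red$log$n_after   # 5
#' @export
filter_constant <- function(data, near_constant_fraction = 0.95) {
  stopifnot(inherits(data, "qsar_data"))
  if (!(near_constant_fraction > 0 && near_constant_fraction <= 1))
    stop("near_constant_fraction must be in (0, 1]")
  x <- data$x
  n <- nrow(x)
  is_const <- apply(x, 2, function(v) max(v) == min(v))
  mode_frac <- apply(x, 2, function(v) max(tabulate(match(v, unique(v)))) / n)
  is_near <- !is_const & mode_frac >= near_constant_fraction
  keep <- !(is_const | is_near)
  if (!any(keep))
    stop("all descriptor columns were removed as (near-)constant")
  structure(list(
    data = data[, keep],
    log = list(removed_constant = colnames(x)[is_const],
               removed_near_constant = colnames(x)[is_near],
               n_before = ncol(x), n_after = sum(keep))
  ), class = "qsar_reduction")
}

#' Resolve collinear descriptor pairs in favour of activity correlation
#'
#' Scans all descriptor pairs for absolute Pearson correlation above
#' \code{r_cut}; for each such pair the member with the larger absolute
#' Pearson correlation to the activity is retained and the other dropped.
#' Pairs are resolved greedily in order of descending |r|, skipping pairs
#' whose members were already dropped, which makes chained collinearity
#' (A~B~C) deterministic. Ties on activity correlation keep the
#' earlier column.
#'
#' @param data a \code{\link{qsar_data}} with activity present.
#' @param r_cut correlation threshold in (0, 1); default 0.9.
#' @return a list of class \code{qsar_reduction} with elements \code{data}
#'   and \code{log}; the log's \code{collinear_pairs} is a data.frame with
#'   one row per resolved pair (kept, dropped, r, r_y_kept, r_y_dropped).
#' @examples
#' s <- synth_qsar(50, 30, n_collinear_pairs = 3, seed = 2)
#' red <- filter_collinear(s$data)
#' red$log$collinear_pairs
#' @export
filter_collinear <- function(data, r_cut = 0.9) {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y))
    stop("filter_collinear requires an activity vector")
  if (!(r_cut > 0 && r_cut < 1)) stop("r_cut must be in (0, 1)")
  x <- data$x
  p <- ncol(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant columns present; run filter_constant() first")
  cm <- stats::cor(x)
  ry <- abs(as.vector(stats::cor(x, data$y)))
  pairs <- which(abs(cm) > r_cut & upper.tri(cm), arr.ind = TRUE)
  log_rows <- list()
  dropped <- logical(p)
  if (nrow(pairs) > 0) {
    ord <- order(-abs(cm[pairs]))
    pairs <- pairs[ord, , drop = FALSE]
    for (q in seq_len(nrow(pairs))) {
      i <- pairs[q, 1]; j <- pairs[q, 2]
      if (dropped[i] || dropped[j]) next
      # keep the member better correlated with activity (ties: earlier column)
      if (ry[j] > ry[i]) { keep <- j; drop <- i } else { keep <- i; drop <- j }
      dropped[drop] <- TRUE
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        kept = colnames(x)[keep], dropped = colnames(x)[drop],
        r = cm[i, j], r_y_kept = ry[keep], r_y_dropped = ry[drop],
        stringsAsFactors = FALSE)
    }
  }
  pair_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(kept = character(0), dropped = character(0), r = numeric(0),
               r_y_kept = numeric(0), r_y_dropped = numeric(0))
  structure(list(
    data = data[, !dropped],
    log = list(collinear_pairs = pair_log,
               n_before = p, n_after = sum(!dropped))
  ), class = "qsar_reduction")
}

#' @export
print.qsar_reduction <- function(x, ...) {
  cat("<qsar_reduction> ", x$log$n_before, " -> ", x$log$n_after,
      " descriptors\n", sep = "")
  invisible(x)
}

#' Full descriptor reduction: constant filter then collinearity filter
#'
#' Convenience wrapper applying \code{\link{filter_constant}} followed by
#' \code{\link{filter_collinear}}, returning the reduced table and both logs.
#'
#' @inheritParams filter_constant
#' @inheritParams filter_collinear
#' @return list with \code{data}, \code{constant_log}, \code{collinear_log}.
#' @export
reduce_descriptors <- function(data, near_constant_fraction = 0.95,
                               r_cut = 0.9) {
  step1 <- filter_constant(data, near_constant_fraction)
  step2 <- filter_collinear(step1$data, r_cut)
  list(data = step2$data, constant_log = step1$log,
       collinear_log = step2$log)
}
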