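#' Descriptor table with activity
#'
#' Light container for a compounds-by-descriptors matrix plus an optional
#' activity vector (pIC50 = -log10 IC50 in molar units). All downstream
#' functions in the package consume this class. Validation is strict:
#' missing or non-finite values are a hard error (no imputation), and
#' compound and descriptor names must be unique.
#'
#' @param x numeric matrix (compounds in rows, descriptors in columns) or a
#'   data.frame coercible to one. Column names are required; row names
#'   default to \code{compound_ids} or \code{C1..Cn}.
#' @param y optional numeric activity vector (pIC50), one value per row.
#' @param compound_ids optional character vector of compound labels.
#' @return an object of class \code{qsar_data}: a list with elements
#'   \code{x} (named matrix) and \code{y} (named numeric or NULL).
#' @examples
#' d <- qsar_data(matrix(rnorm(20), 5, dimnames = list(NULL, paste0("D", 1:4))),
#'                y = rnorm(5))
#' d
#' @export
qsar_data <- function(x, y = NULL, compound_ids = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix or data.frame of descriptors")
  if (is.null(colnames(x)))
    stop("descriptor columns must be named")
  if (anyDuplicated(colnames(x)))
    stop("descriptor names must be unique")
  if (!all(is.finite(x)))
    stop("descriptor matrix contains missing or non-finite values")
  if (!is.null(compound_ids)) {
    rownames(x) <- as.character(compound_ids)
  } else if (is.null(rownames(x))) {
    rownames(x) <- paste0("C", seq_len(nrow(x)))
  }
  if (anyDuplicated(rownames(x)))
    stop("compound ids must be unique")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(x))
      stop("activity length must match the number of compounds")
    if (!all(is.finite(y)))
      stop("activity contains missing or non-finite values")
    names(y) <- rownames(x)
  }
  structure(list(x = x, y = y), class = "qsar_data")
}

#' @export
print.qsar_data <- function(x, ...) {
  cat("<qsar_data> ", nrow(x$x), " compounds x ", ncol(x$x), " descriptors",
      if (is.null(x$y)) " (no activity)" else
        sprintf(", pIC50 range [%.2f, %.2f]", min(x$y), max(x$y)),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.qsar_data <- function(x) dim(x$x)

#' Subset a qsar_data by compounds and/or descriptors
#'
#' @param x a \code{qsar_data}.
#' @param i compound selector (indices, logicals or ids).
#' @param j descriptor selector (indices, logicals or names).
#' @param ... ignored.
#' @return a \code{qsar_data} restricted to the selection.
#' @export
`[.qsar_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$x))
  if (missing(j)) j <- seq_len(ncol(x$x))
  xx <- x$x[i, j, drop = FALSE]
  yy <- if (is.null(x$y)) NULL else x$y[i]
  # selections with replacement (bootstrap resamples) repeat compounds;
  # disambiguate their ids rather than reject them
  if (anyDuplicated(rownames(xx)))
    rownames(xx) <- make.unique(rownames(xx))
  qsar_data(xx, yy)
}

#' @export
as.data.frame.qsar_data <- function(x, ...) {
  df <- data.frame(compound_id = rownames(x$x), x$x,
                   check.names = FALSE, row.names = NULL)
  if (!is.null(x$y)) df$pIC50 <- unname(x$y)
  df
}

#' Read / write a descriptor CSV
#'
#' Plain-text round trip for descriptor tables using the column layout
#' \code{compound_id, <descriptor names>, pIC50} (the activity column is
#' optional on read).
#'
#' @param file path to a CSV file.
#' @param activity_column name of the activity column, default \code{"pIC50"}.
#' @return \code{read_qsar_csv}: a \code{qsar_data}.
#' @export
read_qsar_csv <- function(file, activity_column = "pIC50") {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"compound_id" %in% names(df))
    stop("CSV must have a `compound_id` column")
  ids <- as.character(df$compound_id)
  df$compound_id <- NULL
  y <- NULL
  if (activity_column %in% names(df)) {
    y <- df[[activity_column]]
    df[[activity_column]] <- NULL
  }
  qsar_data(as.matrix(df), y = y, compound_ids = ids)
}

#' @param data a \code{qsar_data} to write.
#' @rdname read_qsar_csv
#' @return \code{write_qsar_csv}: the file path, invisibly.
#' @export
write_qsar_csv <- function(data, file) {
  stopifnot(inherits(data, "qsar_data"))
  utils::write.csv(as.data.frame(data), file, row.names = FALSE)
  invisible(file)
}

# column-wise autoscale using (optionally) reference statistics;
# zero-variance columns scale by 1 so they stay finite
autoscale <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}
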