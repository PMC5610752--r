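#' Hierarchical clustering of compounds in descriptor space
#'
#' Builds the agglomerative dendrogram used for the training/test split.
#' Descriptors are autoscaled (zero mean, unit variance) internally and
#' compounds clustered on Euclidean distance. For N compounds the tree
#' contains N - 1 fusions.
#'
#' @param data a \code{\link{qsar_data}} with at least two compounds.
#' @param linkage agglomeration method passed to \code{\link[stats]{hclust}};
#'   default \code{"complete"} (compact clusters), alternatives
#'   \code{"ward.D2"}, \code{"average"}, \code{"single"}.
#' @return an object of class \code{hclust}.
#' @examples
#' s <- synth_qsar(20, 10, seed = 3)
#' tree <- cluster_compounds(s$data)
#' plot(tree)
#' @export
cluster_compounds <- function(data,
                              linkage = c("complete", "ward.D2",
                                          "average", "single")) {
  stopifnot(inherits(data, "qsar_data"))
  linkage <- match.arg(linkage)
  if (nrow(data$x) < 2)
    stop("clustering needs at least 2 compounds")
  xs <- autoscale(data$x)$x
  stats::hclust(stats::dist(xs, method = "euclidean"), method = linkage)
}

#' Cluster-based training/test split with activity-range coverage
#'
#' Cuts the compound dendrogram into \code{round(n * test_fraction)}
#' clusters and draws one test compound per cluster at random (seeded), so
#' the test set is structurally dispersed across the tree. Compounds
#' carrying the global minimum and maximum activity are always kept in the
#' training set, which guarantees the coverage rule: test activities lie
#' within the training activity range. Clusters whose members are all
#' activity extremes contribute no test compound. The draw is retried
#' (bounded) if coverage were ever violated.
#'
#' @param tree an \code{hclust} over the compounds (see
#'   \code{\link{cluster_compounds}}).
#' @param data the \code{\link{qsar_data}} the tree was built from
#'   (activity required).
#' @param test_fraction fraction of compounds for the test set, in
#'   (0, 0.5]; default 0.2 (7 of 35).
#' @param seed integer seed for the per-cluster draws.
#' @param max_retries bound on coverage retries; default 100.
#' @return an object of class \code{qsar_split}: list with
#'   \code{train_ids}, \code{test_ids}, \code{cluster_of_test} (cut-level
#'   cluster index of each test compound), \code{linkage_method},
#'   \code{n_clusters}, \code{seed}.
#' @examples
#' s <- synth_qsar(35, 30, seed = 5)
#' sp <- make_split(cluster_compounds(s$data), s$data, seed = 5)
#' length(sp$train_ids); length(sp$test_ids)   # 28, 7
#' @export
make_split <- function(tree, data, test_fraction = 0.2, seed = 1,
                       max_retries = 100) {
  stopifnot(inherits(tree, "hclust"), inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("make_split requires activity")
  if (!(test_fraction > 0 && test_fraction <= 0.5))
    stop("test_fraction must be in (0, 0.5]")
  n <- nrow(data$x)
  ids <- rownames(data$x)
  if (length(tree$order) != n)
    stop("tree and table disagree on the number of compounds")
  n_test <- max(1L, round(n * test_fraction))
  k <- min(n_test, n - 2L)
  grp <- stats::cutree(tree, k = k)
  y <- data$y
  extremes <- c(which.min(y), which.max(y))

  set.seed(as.integer(seed))
  for (attempt in seq_len(max_retries)) {
    test_idx <- integer(0)
    cl_of <- integer(0)
    for (g in seq_len(k)) {
      members <- setdiff(which(grp == g), extremes)
      if (length(members) == 0) next
      pick <- if (length(members) == 1) members else sample(members, 1)
      test_idx <- c(test_idx, pick)
      cl_of <- c(cl_of, g)
    }
    ok <- length(test_idx) > 0 &&
      min(y[test_idx]) >= min(y[-test_idx]) &&
      max(y[test_idx]) <= max(y[-test_idx])
    if (ok) {
      return(structure(list(
        train_ids = ids[sort(setdiff(seq_len(n), test_idx))],
        test_ids = ids[sort(test_idx)],
        cluster_of_test = cl_of[order(test_idx)],
        linkage_method = tree$method,
        n_clusters = k,
        seed = as.integer(seed)
      ), class = "qsar_split"))
    }
  }
  stop("could not reach an activity-covering split in ", max_retries,
       " attempts; check for degenerate activity values")
}

#' @export
print.qsar_split <- function(x, ...) {
  cat("<qsar_split> ", length(x$train_ids), " train / ",
      length(x$test_ids), " test (", x$n_clusters, " clusters, ",
      x$linkage_method, " linkage)\n", sep = "")
  invisible(x)
}

# row indices of the training / test compounds of a split in `data`
split_rows <- function(split, data) {
  ids <- rownames(data$x)
  list(train = match(split$train_ids, ids),
       test = match(split$test_ids, ids))
}
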