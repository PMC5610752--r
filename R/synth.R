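#' Simulate a QSAR descriptor table with planted ground truth
#'
#' Generates a synthetic compounds-by-descriptors matrix with the statistical
#' structure a descriptor-reduction / subset-selection workflow assumes:
#' a small informative subset driving the activity linearly (optionally with
#' a smooth interaction term), exactly constant columns, near-constant
#' columns (one value repeated in a >95\% fraction of rows), strongly
#' collinear column pairs, and independent standard-normal noise descriptors.
#' Activity is expressed as pIC50 and spans \code{activity_range} before
#' noise is added. The generator is bit-for-bit reproducible under a fixed
#' seed.
#'
#' Descriptor marginals are standard normal prior to planting structure,
#' matching the autoscaled-descriptor assumption of the downstream models.
#' Collinear partners are built as \code{x2 = x1 + N(0, s2)} with \code{s2}
#' chosen so the population correlation equals \code{collinear_r}.
#'
#' @param n_compounds number of compounds (rows). Default 35, the size of a
#'   typical small congeneric inhibitor series.
#' @param n_descriptors total descriptor pool size (columns).
#' @param k_informative number of descriptors that truly drive activity.
#' @param n_constant number of exactly constant columns.
#' @param n_near_constant number of near-constant columns (mode frequency
#'   at least 0.95 when \code{n_compounds >= 20}).
#' @param n_collinear_pairs number of planted collinear pairs.
#' @param noise_sd Gaussian noise SD added to the activity, in pIC50 units.
#' @param coefficient_range magnitude interval for true linear coefficients
#'   (signs are random).
#' @param activity_range target pIC50 interval for the noiseless signal.
#' @param collinear_r target population correlation of planted pairs.
#' @param nonlinear if TRUE, add an interaction term \code{g * x_i * x_j}
#'   between two informative descriptors, with \code{g} scaled so the term
#'   carries 20\% of the linear signal variance.
#' @param seed integer RNG seed.
#' @return an object of class \code{qsar_synth}: a list with
#'   \code{data} (a \code{\link{qsar_data}} with activity),
#'   \code{true_subset} (names of informative descriptors),
#'   \code{true_coefficients} (named vector, first element
#'   \code{"(Intercept)"}, on the final pIC50 scale),
#'   \code{nonlinear_term} (NULL, or list with \code{pair} and \code{gamma}),
#'   \code{planted} (names of constant / near-constant / collinear columns),
#'   \code{noise_sd} and the call parameters.
#' @examples
#' s <- synth_qsar(n_compounds = 35, n_descriptors = 60, seed = 1)
#' s$true_subset
#' range(s$data$y)
#' @export
synth_qsar <- function(n_compounds = 35, n_descriptors = 100,
                       k_informative = 5, n_constant = 0,
                       n_near_constant = 0, n_collinear_pairs = 0,
                       noise_sd = 0.2, coefficient_range = c(0.5, 2),
                       activity_range = c(4, 8), collinear_r = 0.95,
                       nonlinear = FALSE, seed = 1) {
  n <- as.integer(n_compounds); p <- as.integer(n_descriptors)
  k <- as.integer(k_informative)
  if (k < 1) stop("k_informative must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n < k + 2) stop("n_compounds must be >= k_informative + 2")
  n_special <- k + n_constant + n_near_constant + 2L * n_collinear_pairs
  if (n_special > p)
    stop("k_informative + n_constant + n_near_constant + 2*n_collinear_pairs ",
         "must not exceed n_descriptors")
  if (length(activity_range) != 2 || diff(activity_range) <= 0)
    stop("activity_range must be an increasing interval")
  if (!(collinear_r > 0 && collinear_r < 1))
    stop("collinear_r must be in (0, 1)")

  set.seed(as.integer(seed))
  dnames <- sprintf("D%04d", seq_len(p))
  x <- matrix(stats::rnorm(n * p), n, p, dimnames = list(
    sprintf("C%03d", seq_len(n)), dnames))

  # assign column roles in one seeded draw
  roles <- sample.int(p, n_special)
  idx_inf <- roles[seq_len(k)]
  off <- k
  idx_const <- roles[seq_len(n_constant) + off]; off <- off + n_constant
  idx_near <- roles[seq_len(n_near_constant) + off]; off <- off + n_near_constant
  idx_pair <- if (n_collinear_pairs > 0)
    matrix(roles[off + seq_len(2L * n_collinear_pairs)], ncol = 2) else
    matrix(integer(0), 0, 2)

  for (j in idx_const) x[, j] <- stats::rnorm(1)
  n_flip <- max(1L, floor(n * 0.05))
  for (j in idx_near) {
    mode_val <- stats::rnorm(1)
    x[, j] <- mode_val
    flip <- sample.int(n, n_flip)
    x[flip, j] <- mode_val + stats::rnorm(n_flip)
  }
  # x2 = x1 + noise with var s2 = 1/r^2 - 1 so population cor = collinear_r;
  # the noise draw is repeated (seeded, bounded) until the SAMPLE correlation
  # exceeds 0.9 so planted pairs are always detectable at the standard cut
  s_pair <- sqrt(1 / collinear_r^2 - 1)
  for (q in seq_len(nrow(idx_pair))) {
    for (try in 1:100) {
      cand <- x[, idx_pair[q, 1]] + stats::rnorm(n, sd = s_pair)
      if (abs(stats::cor(cand, x[, idx_pair[q, 1]])) > 0.9) break
    }
    x[, idx_pair[q, 2]] <- cand
  }

  beta <- stats::runif(k, coefficient_range[1], coefficient_range[2]) *
    sample(c(-1, 1), k, replace = TRUE)
  signal <- drop(x[, idx_inf, drop = FALSE] %*% beta)
  gamma <- 0
  pair_nl <- NULL
  if (isTRUE(nonlinear)) {
    pair_nl <- idx_inf[1:2]
    if (k < 2) stop("nonlinear term needs k_informative >= 2")
    inter <- x[, pair_nl[1]] * x[, pair_nl[2]]
    gamma <- sqrt(0.2 * stats::var(signal) / stats::var(inter))
    signal <- signal + gamma * inter
  }
  # affine map of the noiseless signal onto activity_range; coefficients are
  # reported on the mapped scale so the linear truth stays exact
  sc <- diff(activity_range) / diff(range(signal))
  intercept <- activity_range[1] - min(signal) * sc
  beta <- beta * sc
  gamma <- gamma * sc
  y0 <- intercept + sc * signal
  y <- y0 + stats::rnorm(n, sd = noise_sd)

  truth <- c(intercept, beta)
  names(truth) <- c("(Intercept)", dnames[idx_inf])
  structure(list(
    data = qsar_data(x, y),
    true_subset = dnames[idx_inf],
    true_coefficients = truth,
    nonlinear_term = if (isTRUE(nonlinear))
      list(pair = dnames[pair_nl], gamma = gamma) else NULL,
    planted = list(constant = dnames[idx_const],
                   near_constant = dnames[idx_near],
                   collinear_pairs = matrix(dnames[idx_pair],
                                            ncol = 2,
                                            dimnames = list(NULL, c("base", "partner")))),
    noise_sd = noise_sd,
    activity_range = activity_range,
    seed = as.integer(seed)
  ), class = "qsar_synth")
}

#' @export
print.qsar_synth <- function(x, ...) {
  cat("<qsar_synth> ", nrow(x$data$x), " compounds x ", ncol(x$data$x),
      " descriptors; informative: ", paste(x$true_subset, collapse = ", "),
      "; noise_sd = ", x$noise_sd, "\n", sep = "")
  invisible(x)
}
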