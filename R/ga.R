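#' Genetic-algorithm descriptor subset selection
#'
#' Wrapper feature selection for QSAR: searches for the fixed-size
#' descriptor subset maximizing a cross-validated fitness of an ordinary
#' least-squares model. Chromosomes are sets of \code{subset_size} distinct
#' descriptor indices; the population evolves by tournament selection,
#' uniform (union-resampling) crossover repaired to fixed size, single-gene
#' mutation, and elitism. Running the search several times from different
#' seeded populations (\code{n_runs > 1}) yields a ranked list of
#' alternative models, the usual way competing descriptor combinations are
#' reported. Deterministic under a fixed seed.
#'
#' Fitness defaults to leave-one-out Q2 of the candidate MLR (computed by
#' the exact hat-matrix identity); \code{"press"} (negated) and training
#' \code{"r2"} are also available. Equal-fitness subsets are ranked
#' lexicographically by descriptor name so results are reproducible.
#'
#' @param data a \code{\link{qsar_data}} with activity — training rows only.
#' @param subset_size number of descriptors per model (default 5).
#' @param population_size chromosomes per generation (default 50).
#' @param n_generations generations per run (default 100).
#' @param crossover_rate probability a child is produced by crossover rather
#'   than cloning (default 0.8).
#' @param mutation_rate per-child probability of a single-gene swap
#'   (default 0.1).
#' @param elitism number of top chromosomes copied unchanged (default 2).
#' @param fitness fitness criterion: \code{"q2_loo"} (default),
#'   \code{"press"}, or \code{"r2"}.
#' @param n_runs independent GA restarts (default 1).
#' @param seed integer seed; run r uses \code{seed + r - 1}.
#' @return an object of class \code{ga_result}: \code{runs} — a list of
#'   \code{list(subset, fitness, generation_found, trajectory)} (the
#'   trajectory holds the best population fitness per generation, starting
#'   at generation 0) sorted best first —
#'   plus \code{best} (index, always 1 after ranking), the fitness name and
#'   the call parameters.
#' @examples
#' s <- synth_qsar(30, 12, k_informative = 3, noise_sd = 0.1, seed = 1)
#' ga <- ga_select(s$data, subset_size = 3, n_generations = 30, seed = 1)
#' ga$runs[[ga$best]]$subset
#' @export
ga_select <- function(data, subset_size = 5, population_size = 50,
                      n_generations = 100, crossover_rate = 0.8,
                      mutation_rate = 0.1, elitism = 2,
                      fitness = c("q2_loo", "press", "r2"),
                      n_runs = 1, seed = 1) {
  stopifnot(inherits(data, "qsar_data"))
  if (is.null(data$y)) stop("ga_select requires activity")
  fitness <- match.arg(fitness)
  p <- ncol(data$x)
  k <- as.integer(subset_size)
  if (k < 1 || k > p) stop("subset_size must be in 1..ncol(data)")
  if (population_size < 2) stop("population_size must be >= 2")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1)
    stop("rates must be probabilities")
  if (nrow(data$x) <= k + 1)
    stop("need more training compounds than subset_size + 1")
  x <- data$x; y <- data$y

  cache <- new.env(parent = emptyenv())
  eval_subset <- function(cols) {       # cols sorted integer vector
    key <- paste(cols, collapse = ",")
    val <- cache[[key]]
    if (!is.null(val)) return(val)
    m <- press_mlr(x[, cols, drop = FALSE], y)
    val <- switch(fitness, q2_loo = m$q2, press = -m$press, r2 = m$r2)
    cache[[key]] <- val
    val
  }

  run_one <- function(run_seed) {
    set.seed(run_seed)
    pop <- t(replicate(population_size, sort(sample.int(p, k))))
    fit <- apply(pop, 1, eval_subset)
    best_fit <- max(fit)
    best_chrom <- pop[which.max(fit), ]
    best_gen <- 0L
    if (k == p) {   # single possible chromosome: nothing to evolve
      return(list(subset = sort(colnames(x)[best_chrom]),
                  fitness = best_fit, generation_found = 0L,
                  trajectory = best_fit))
    }
    trajectory <- numeric(n_generations + 1L)
    trajectory[1L] <- max(fit)
    for (gen in seq_len(n_generations)) {
      ord <- order(fit, decreasing = TRUE)
      new_pop <- pop[ord[seq_len(min(elitism, population_size))], ,
                     drop = FALSE]
      while (nrow(new_pop) < population_size) {
        tourn <- function() {
          cand <- sample.int(population_size, 2)
          pop[cand[which.max(fit[cand])], ]
        }
        p1 <- tourn()
        child <- if (stats::runif(1) < crossover_rate) {
          pool <- union(p1, tourn())   # uniform crossover + size repair
          sort(sample(pool, k))
        } else p1
        if (stats::runif(1) < mutation_rate) {
          out <- sample.int(k, 1)
          child[out] <- sample(setdiff(seq_len(p), child), 1)
          child <- sort(child)
        }
        new_pop <- rbind(new_pop, child)
      }
      pop <- new_pop
      fit <- apply(pop, 1, eval_subset)
      trajectory[gen + 1L] <- max(fit)
      if (max(fit) > best_fit) {
        best_fit <- max(fit)
        best_chrom <- pop[which.max(fit), ]
        best_gen <- gen
      }
    }
    list(subset = sort(colnames(x)[best_chrom]),
         fitness = best_fit, generation_found = best_gen,
         trajectory = trajectory)
  }

  runs <- lapply(seq_len(n_runs), function(r) run_one(as.integer(seed) + r - 1L))
  keys <- vapply(runs, function(r) paste(r$subset, collapse = "|"), "")
  fits <- vapply(runs, `[[`, numeric(1), "fitness")
  ord <- order(-fits, keys)
  structure(list(runs = runs[ord], best = 1L, fitness_name = fitness,
                 subset_size = k, n_runs = n_runs, seed = as.integer(seed)),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> ", x$n_runs, " run(s), subset size ", x$subset_size,
      ", fitness = ", x$fitness_name, "\n", sep = "")
  for (i in seq_along(x$runs)) {
    r <- x$runs[[i]]
    cat(sprintf("  %s%2d: %.4f  [%s] (gen %d)\n",
                if (i == x$best) "*" else " ", i, r$fitness,
                paste(r$subset, collapse = ", "), r$generation_found))
  }
  invisible(x)
}

#' Best descriptor subset of a GA result
#'
#' @param ga a \code{ga_result}.
#' @return character vector of descriptor names of the top-ranked run.
#' @export
ga_best_subset <- function(ga) {
  stopifnot(inherits(ga, "ga_result"))
  ga$runs[[ga$best]]$subset
}
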