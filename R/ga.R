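#' GA configuration
#'
#' Parameters of the genetic-algorithm stage. Defaults follow the standard
#' operating point of the method: population 1500, at most 200 generations,
#' crossover probability 0.18, mutation probability 0.01, fitness threshold
#' 0.5, elitist preservation of the single best individual.
#'
#' @param population_size Number of chromosomes (>= 2).
#' @param generations Maximum number of generations.
#' @param crossover_prob Per-pair probability of one-point crossover.
#' @param mutation_prob Per-gene probability of uniform resampling.
#' @param fitness_threshold Evolution stops once the best chromosome's
#'   fitness reaches this value.
#' @param window Window size K; scales the oscillatory fitness term.
#' @param elite_count Individuals copied unchanged into the next generation.
#' @param chromosome_length Genes per chromosome (default 8, one per sensor).
#' @param seed_fraction Fraction of the initial population drawn from
#'   observed feature vectors (the rest is uniform on `[0,1]^L`). Default 1:
#'   the population is created from the sensors' values.
#' @param jitter_sd Gaussian jitter added to seeded individuals.
#' @param seed Optional integer RNG seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 1500, generations = 200,
                      crossover_prob = 0.18, mutation_prob = 0.01,
                      fitness_threshold = 0.5, window = 10, elite_count = 1,
                      chromosome_length = 8, seed_fraction = 1,
                      jitter_sd = 0.01, seed = NULL) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              crossover_prob = crossover_prob, mutation_prob = mutation_prob,
              fitness_threshold = fitness_threshold, window = window,
              elite_count = as.integer(elite_count),
              chromosome_length = as.integer(chromosome_length),
              seed_fraction = seed_fraction, jitter_sd = jitter_sd, seed = seed)
  if (cfg$population_size < 2) stop("population_size must be >= 2", call. = FALSE)
  if (cfg$generations < 0) stop("generations must be >= 0", call. = FALSE)
  for (p in c("crossover_prob", "mutation_prob", "seed_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(sprintf("%s must be in [0,1]", p), call. = FALSE)
  }
  if (cfg$fitness_threshold < 0) stop("fitness_threshold must be >= 0", call. = FALSE)
  if (cfg$window < 1) stop("window must be >= 1", call. = FALSE)
  if (cfg$elite_count < 0 || cfg$elite_count >= cfg$population_size) {
    stop("elite_count must be in [0, population_size)", call. = FALSE)
  }
  if (cfg$chromosome_length < 1) stop("chromosome_length must be >= 1", call. = FALSE)
  class(cfg) <- "ga_config"
  cfg
}

#' Oscillatory GA fitness function
#'
#' Per-gene fitness \eqn{f(x) = x + K |\sin(32 x)|} on the domain
#' \eqn{0 \le x < \pi} (radians). The linear term rewards large normalized
#' sensor values; the rectified sine term, scaled by the preprocessing window
#' K, superimposes ~10 oscillations on the unit interval so that many local
#' optima compete. Since genes live in `[0,1]` the domain constraint holds
#' automatically.
#'
#' @param x Numeric vector of candidate values in `[0, pi)`.
#' @param K Window size (>= 1).
#' @return `x + K * abs(sin(32 * x))`, vectorized.
#' @examples
#' ga_fitness(0, 10)        # 0
#' ga_fitness(pi / 32, 10)  # pi/32: the sine term vanishes
#' @export
ga_fitness <- function(x, K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("'K' must be >= 1", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0) || any(x >= pi)) {
    stop("fitness domain is 0 <= x < pi", call. = FALSE)
  }
  x + K * abs(sin(32 * x))
}

#' Fitness of a whole chromosome
#'
#' The per-gene fitness [ga_fitness()] averaged over the genes. Averaging
#' (rather than summing) keeps the value comparable across chromosome
#' lengths, so the same 0.5 threshold applies whatever L is.
#'
#' @param genes Numeric vector of genes in `[0, 1]`.
#' @param K Window size.
#' @return Scalar fitness >= 0.
#' @export
chromosome_fitness <- function(genes, K) mean(ga_fitness(genes, K))

.population_fitness <- function(genes, K) {
  # rowMeans over the per-gene fitness matrix; genes is N x L
  rowMeans(matrix(ga_fitness(as.vector(genes), K), nrow = nrow(genes)))
}

#' Initialize a GA population
#'
#' A fraction `seed_fraction` of the chromosomes is drawn (with replacement)
#' from the rows of `features` — the observed normalized sensor vectors —
#' plus Gaussian jitter clipped back to `[0,1]`; the remainder is uniform on
#' `[0,1]^L`.
#'
#' @param features Matrix of observed feature vectors (rows) in `[0,1]`, or
#'   `NULL` when `seed_fraction = 0`.
#' @param config A [ga_config()].
#' @return An object of class `ga_population`: list with `genes`
#'   (population_size x L matrix) and `fitness` (per-chromosome, filled by
#'   [ga_evolve()]; `NULL` here).
#' @export
init_population <- function(features, config) {
  stopifnot(inherits(config, "ga_config"))
  N <- config$population_size
  L <- config$chromosome_length
  n_seeded <- round(config$seed_fraction * N)
  if (n_seeded > 0) {
    if (is.null(features) || nrow(as.matrix(features)) == 0L) {
      stop("seeding requested but no feature vectors supplied", call. = FALSE)
    }
    features <- as.matrix(features)
    if (ncol(features) != L) stop("feature vectors must have chromosome_length columns", call. = FALSE)
    if (any(features < 0) || any(features > 1)) stop("features must lie in [0,1]", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  genes <- matrix(stats::runif(N * L), N, L)
  if (n_seeded > 0) {
    rows <- sample.int(nrow(features), n_seeded, replace = TRUE)
    jit <- if (config$jitter_sd > 0) stats::rnorm(n_seeded * L, 0, config$jitter_sd) else 0
    genes[seq_len(n_seeded), ] <- pmin(pmax(features[rows, , drop = FALSE] + jit, 0), 1)
  }
  structure(list(genes = genes, fitness = NULL), class = "ga_population")
}

#' Roulette-wheel parent selection
#'
#' Draws two parent indices independently, each with probability proportional
#' to fitness; when the total fitness is zero the draw is uniform.
#'
#' @param fitness Numeric vector of non-negative fitness values (length >= 2).
#' @return Integer vector of two indices.
#' @export
ga_select <- function(fitness) {
  n <- length(fitness)
  if (n < 2L) stop("need a population of at least 2", call. = FALSE)
  if (any(fitness < 0)) stop("fitness must be non-negative", call. = FALSE)
  tot <- sum(fitness)
  prob <- if (tot > 0) fitness / tot else rep(1 / n, n)
  c(sample.int(n, 1L, prob = prob), sample.int(n, 1L, prob = prob))
}

#' One-point crossover
#'
#' Cuts both parents at the same uniformly random point in `{1, ..., L-1}`
#' and exchanges the tails, so at every locus the pair of offspring carries
#' the same multiset of genes as the parents. Chromosomes of length 1 are
#' cloned (no interior cut exists).
#'
#' @param a,b Parent gene vectors of equal length.
#' @param cut Optional fixed cut point (genes `1..cut` keep their parent).
#' @return List of two offspring gene vectors.
#' @export
ga_crossover <- function(a, b, cut = NULL) {
  L <- length(a)
  if (length(b) != L) stop("parents must have equal length", call. = FALSE)
  if (L < 2L) return(list(a, b))
  if (is.null(cut)) cut <- sample.int(L - 1L, 1L)
  if (cut < 1L || cut > L - 1L) stop("cut must be in 1..L-1", call. = FALSE)
  tail_idx <- (cut + 1L):L
  o1 <- a; o2 <- b
  o1[tail_idx] <- b[tail_idx]
  o2[tail_idx] <- a[tail_idx]
  list(o1, o2)
}

#' Uniform-resampling mutation
#'
#' Each gene is independently replaced by a fresh uniform draw on `[0,1]`
#' with probability `pm`.
#'
#' @param genes Gene vector.
#' @param pm Per-gene mutation probability in `[0,1]`.
#' @return Mutated gene vector.
#' @export
ga_mutate <- function(genes, pm) {
  if (pm < 0 || pm > 1) stop("'pm' must be in [0,1]", call. = FALSE)
  if (pm == 0) return(genes)
  hit <- stats::runif(length(genes)) < pm
  if (any(hit)) genes[hit] <- stats::runif(sum(hit))
  genes
}

#' Run the genetic algorithm
#'
#' Generational loop with elitist preservation: the `elite_count` best
#' chromosomes are copied unchanged, the rest of the next generation is
#' produced by roulette-wheel selection, one-point crossover with probability
#' `crossover_prob` (pairs not crossing over are cloned), and per-gene
#' mutation. Evolution stops as soon as the best fitness reaches
#' `fitness_threshold`, or after `generations` generations. Elitism makes the
#' best fitness non-decreasing across generations.
#'
#' @param features Observed feature-vector matrix passed to
#'   [init_population()], or a ready-made `ga_population`.
#' @param config A [ga_config()].
#' @return List with `population` (final `ga_population` with fitness),
#'   `best_genes`, `best_fitness`, `converged` (threshold reached),
#'   `generations_run`, and `history` — a data.frame
#'   (`generation`, `best_fitness`, `mean_fitness`), generation 0 being the
#'   initial population.
#' @export
ga_evolve <- function(features, config) {
  stopifnot(inherits(config, "ga_config"))
  pop <- if (inherits(features, "ga_population")) {
    if (!is.null(config$seed)) set.seed(as.integer(config$seed))
    features
  } else {
    init_population(features, config)
  }
  genes <- pop$genes
  N <- nrow(genes)
  K <- config$window
  history <- data.frame(generation = integer(), best_fitness = numeric(),
                        mean_fitness = numeric())
  fit <- .population_fitness(genes, K)
  gen <- 0L
  repeat {
    history <- rbind(history, data.frame(generation = gen, best_fitness = max(fit),
                                         mean_fitness = mean(fit)))
    if (max(fit) >= config$fitness_threshold || gen >= config$generations) break
    ord <- order(fit, decreasing = TRUE)
    nxt <- matrix(0, N, ncol(genes))
    n_elite <- config$elite_count
    if (n_elite > 0) nxt[seq_len(n_elite), ] <- genes[ord[seq_len(n_elite)], , drop = FALSE]
    i <- n_elite
    while (i < N) {
      par <- ga_select(fit)
      kids <- if (stats::runif(1) < config$crossover_prob) {
        ga_crossover(genes[par[1L], ], genes[par[2L], ])
      } else {
        list(genes[par[1L], ], genes[par[2L], ])
      }
      for (k in kids) {
        if (i < N) {
          i <- i + 1L
          nxt[i, ] <- ga_mutate(k, config$mutation_prob)
        }
      }
    }
    genes <- nxt
    fit <- .population_fitness(genes, K)
    gen <- gen + 1L
  }
  best <- which.max(fit)
  list(population = structure(list(genes = genes, fitness = fit), class = "ga_population"),
       best_genes = genes[best, ], best_fitness = fit[best],
       converged = fit[best] >= config$fitness_threshold,
       generations_run = gen, history = history)
}

#' GA-denoised feature vector of a sensor frame
#'
#' Extracts the event's observed feature vectors — the smoothed, normalized
#' eight-channel values at every gradient epoch `t = K, 2K, ...` — seeds the
#' GA population from them, evolves, and returns the elite chromosome. The
#' elite is the event's denoised feature vector and is what the neural
#' network stage consumes.
#'
#' @param frame A [sensor_frame()].
#' @param K Window size.
#' @param saturations Per-channel saturations (length 1 or 8).
#' @param config A [ga_config()]; its `window` is overridden by `K`.
#' @return Named numeric vector of 8 denoised features in `[0,1]`.
#' @export
ga_denoise <- function(frame, K, saturations, config = ga_config()) {
  feats <- epoch_features(frame, K, saturations)
  config$window <- K
  res <- ga_evolve(feats, config)
  stats::setNames(res$best_genes, ENOSE_CHANNELS)
}

#' Per-epoch feature vectors of a frame
#'
#' The smoothed, normalized eight-channel values sampled at the gradient
#' epochs `t = K, 2K, ...` — one row per epoch. These are the observation
#' vectors the GA population is seeded from.
#'
#' @inheritParams ga_denoise
#' @return Matrix (epochs x 8) with values in `[0,1]`.
#' @export
epoch_features <- function(frame, K, saturations) {
  if (!inherits(frame, "sensor_frame")) stop("'frame' must be a sensor_frame", call. = FALSE)
  nm <- normalize_series(smma(frame$values, K), rep_len(saturations, 8L))
  n <- nrow(nm)
  if (n <= K) stop("frame shorter than one window", call. = FALSE)
  t_eval <- seq.int(K, n - 1L, by = K)
  nm[t_eval + 1L, , drop = FALSE]
}

#' Write a GA evolution history to CSV
#'
#' @param history The `history` data.frame from [ga_evolve()].
#' @param path Output CSV path (columns `generation,best_fitness,mean_fitness`).
#' @return `path`, invisibly.
#' @export
write_ga_history <- function(history, path) {
  utils::write.csv(history[, c("generation", "best_fitness", "mean_fitness")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
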