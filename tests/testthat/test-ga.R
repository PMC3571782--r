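test_that("oscillatory fitness matches hand-computed values and its bounds", {
  expect_equal(ga_fitness(0, 10), 0)
  expect_equal(ga_fitness(pi / 32, 4), pi / 32, tolerance = 1e-12)
  expect_equal(ga_fitness(0.5, 3), 0.5 + 3 * abs(sin(16)))
  expect_equal(ga_fitness(0.5, 3), 1.36371, tolerance = 1e-4)
  set.seed(1)
  x <- runif(300, 0, pi - 1e-9)
  f <- ga_fitness(x, 7)
  expect_true(all(f >= x & f <= x + 7))
  expect_error(ga_fitness(-0.1, 3), "domain")
  expect_error(ga_fitness(pi, 3), "domain")
  expect_error(ga_fitness(0.2, 0), "K")
})

test_that("chromosome fitness is the mean per-gene fitness", {
  expect_equal(chromosome_fitness(rep(0, 8), 10), 0)
  expect_equal(chromosome_fitness(rep(pi / 32, 8), 10), pi / 32, tolerance = 1e-12)
  expect_equal(chromosome_fitness(c(0, 0.5), 3), (0 + 0.5 + 3 * abs(sin(16))) / 2)
})

test_that("population initialization honours size, seeding, and determinism", {
  v <- matrix(runif(8), 1, 8)
  cfg <- ga_config(seed = 2)
  pop <- init_population(v, cfg)
  expect_equal(dim(pop$genes), c(1500L, 8L))
  # zero jitter, full seeding from one vector: every row equals that vector
  cfg0 <- ga_config(population_size = 40, jitter_sd = 0, seed = 2)
  pop0 <- init_population(v, cfg0)
  expect_true(all(apply(pop0$genes, 1, function(r) all(r == v[1, ]))))
  expect_identical(init_population(v, cfg)$genes, init_population(v, cfg)$genes)
  expect_error(init_population(NULL, cfg0), "seeding")
  # unseeded uniform mode works without features
  cfgU <- ga_config(population_size = 10, seed_fraction = 0, seed = 1)
  expect_equal(dim(init_population(NULL, cfgU)$genes), c(10L, 8L))
})

test_that("roulette selection follows the fitness mass", {
  expect_true(all(ga_select(c(0, 5, 0)) == 2L))
  set.seed(3)
  draws <- replicate(5000, ga_select(c(3, 1)))
  p1 <- mean(draws == 1L)
  expect_lt(abs(p1 - 0.75), 4 * sqrt(0.75 * 0.25 / 10000))
  draws0 <- replicate(5000, ga_select(c(0, 0, 0, 0)))
  freqs <- tabulate(draws0, 4) / length(draws0)
  expect_true(all(abs(freqs - 0.25) < 4 * sqrt(0.25 * 0.75 / 10000)))
  expect_error(ga_select(1), "at least 2")
})

test_that("one-point crossover exchanges tails and preserves locus multisets", {
  a <- rep(0, 4); b <- rep(1, 4)
  expect_equal(ga_crossover(a, b, cut = 1), list(c(0, 1, 1, 1), c(1, 0, 0, 0)))
  for (cut in 1:3) {
    kids <- ga_crossover(a, b, cut = cut)
    expect_equal(kids[[1]], c(rep(0, cut), rep(1, 4 - cut)))
  }
  expect_equal(ga_crossover(a, a), list(a, a))
  set.seed(6)
  for (i in 1:20) {
    p1 <- runif(8); p2 <- runif(8)
    kids <- ga_crossover(p1, p2)
    for (l in 1:8) {
      expect_setequal(c(kids[[1]][l], kids[[2]][l]), c(p1[l], p2[l]))
    }
  }
  expect_error(ga_crossover(1:3 / 10, 1:4 / 10), "equal length")
})

test_that("mutation resamples genes at the configured rate", {
  g <- runif(8)
  expect_identical(ga_mutate(g, 0), g)
  set.seed(7)
  expect_true(all(ga_mutate(g, 1) != g))
  set.seed(8)
  counts <- replicate(20000, sum(ga_mutate(g, 0.01) != g))
  expect_lt(abs(mean(counts) - 0.08),
            4 * sqrt(8 * 0.01 * 0.99 / 20000))
})

test_that("evolution stops immediately once the threshold is already met", {
  v <- matrix(rep(0.9, 8), 1, 8)  # fitness ~0.9 + K|sin| >= 0.5
  cfg <- ga_config(population_size = 20, jitter_sd = 0, seed = 1)
  res <- ga_evolve(v, cfg)
  expect_true(res$converged)
  expect_equal(res$generations_run, 0L)
  expect_equal(nrow(res$history), 1L)
})

test_that("elitism keeps the best fitness non-decreasing over generations", {
  # unreachable threshold forces the full generational loop
  cfg <- ga_config(population_size = 50, generations = 30,
                   fitness_threshold = 1e6, window = 10,
                   seed_fraction = 0, seed = 12)
  res <- ga_evolve(NULL, cfg)
  expect_equal(res$generations_run, 30L)
  expect_true(all(diff(res$history$best_fitness) >= -1e-12))
  expect_true(all(res$population$genes >= 0 & res$population$genes <= 1))
})

test_that("GA denoising returns an in-range elite vector deterministically", {
  fr <- generate_event(builtin_class_specs()$fish_day3, 200, seed = 4)
  cfg <- ga_config(population_size = 200, seed = 9)
  e1 <- ga_denoise(fr, 10, 5, cfg)
  e2 <- ga_denoise(fr, 10, 5, cfg)
  expect_identical(e1, e2)
  expect_named(e1, ENOSE_CHANNELS)
  expect_true(all(e1 >= 0 & e1 <= 1))
})

test_that("GA history CSV has the documented columns", {
  cfg <- ga_config(population_size = 20, generations = 3,
                   fitness_threshold = 1e6, seed_fraction = 0, seed = 1)
  res <- ga_evolve(NULL, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ga_history(res$history, path)
  expect_identical(readLines(path, n = 1), "generation,best_fitness,mean_fitness")
})
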