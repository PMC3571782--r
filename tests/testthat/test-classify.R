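make_profile <- function(values, K = 10) {
  # wrap a gradient matrix directly as a profile on the t = K, 2K, ... grid
  structure(list(t = seq_len(nrow(values)) * K,
                 values = `colnames<-`(values, ENOSE_CHANNELS),
                 K = as.integer(K), role = "test", label = NULL),
            class = "gradient_profile")
}

make_record <- function(values, label = "ref", K = 10) {
  structure(list(label = label,
                 signature = make_profile(values, K),
                 elite = runif(8), provenance = 1L),
            class = "reference_record")
}

test_that("channel similarity scores sign and relative closeness", {
  expect_equal(channel_similarity(0.07, 0.07), 1)
  expect_equal(channel_similarity(0.1, -0.1), 0)
  expect_equal(channel_similarity(0.08, 0.10), 0.8, tolerance = 1e-12)
  expect_equal(channel_similarity(-0.08, -0.10), 0.8, tolerance = 1e-12)
  # flat gradients (below eps) only match each other
  expect_equal(channel_similarity(1e-9, 1e-9), 1)
  expect_equal(channel_similarity(1e-9, 0.1), 0)
  expect_true(all(channel_similarity(runif(50, -1, 1), runif(50, -1, 1)) >= 0))
  expect_true(all(channel_similarity(runif(50, -1, 1), runif(50, -1, 1)) <= 1))
})

test_that("the 6-of-8 decision rule fires exactly at six matched channels", {
  base <- matrix(0.1, 5, 8)
  rec <- make_record(base)
  expect_true(match_record(make_profile(base), rec)$success)
  expect_equal(match_record(make_profile(base), rec)$n_matched, 8L)
  # flip channels to similarity 0 one at a time
  for (bad in 0:4) {
    q <- base
    if (bad > 0) q[, seq_len(bad)] <- -0.1
    r <- match_record(make_profile(q), rec)
    expect_equal(r$n_matched, 8L - bad)
    expect_equal(r$success, (8L - bad) >= 6L)
  }
  # exactly 6 at similarity >= 0.8, two below threshold
  q <- base
  q[, 1:2] <- 0.05       # similarity 0.5
  q[, 3:8] <- 0.085      # similarity 0.85
  r <- match_record(make_profile(q), rec, sim_threshold = 0.8)
  expect_equal(r$n_matched, 6L)
  expect_true(r$success)
  expect_false(match_record(make_profile(q), rec, min_channels = 7)$success)
})

test_that("the per-epoch condition must hold at every shared epoch", {
  base <- matrix(0.1, 6, 8)
  q <- base
  q[4, 5] <- -0.1  # one bad epoch on one channel
  r <- match_record(make_profile(q), make_record(base))
  expect_equal(r$n_matched, 7L)
  expect_false(r$channel_match[5])
})

test_that("strict inequality and window mismatches are handled", {
  base <- matrix(0.5, 4, 8)
  q <- base; q[, 1:8] <- 0.375  # similarity exactly 0.75 (dyadic, no rounding)
  rec <- make_record(base)
  expect_equal(match_record(make_profile(q), rec, sim_threshold = 0.75)$n_matched, 8L)
  expect_equal(match_record(make_profile(q), rec, sim_threshold = 0.75,
                            strict_inequality = TRUE)$n_matched, 0L)
  expect_error(match_record(make_profile(q, K = 5), rec), "mismatch")
})

test_that("threshold monotonicity: stricter settings never help", {
  set.seed(13)
  for (i in 1:10) {
    q <- make_profile(matrix(rnorm(40, 0.05, 0.05), 5, 8))
    rec <- make_record(matrix(rnorm(40, 0.05, 0.05), 5, 8))
    n_prev <- Inf
    for (thr in c(0.5, 0.7, 0.8, 0.9, 0.99)) {
      n <- match_record(q, rec, sim_threshold = thr)$n_matched
      expect_lte(n, n_prev)
      n_prev <- n
    }
    for (mc in 1:8) {
      r <- match_record(q, rec, min_channels = mc)
      if (!r$success) {
        expect_false(match_record(q, rec, min_channels = mc + 1)$success)
      }
    }
  }
})

test_that("database matching ranks the true record first and falls back to unidentified", {
  sig_a <- matrix(0.10, 5, 8)
  sig_b <- matrix(0.20, 5, 8)
  db <- structure(list(records = list(a = make_record(sig_a, "a"),
                                      b = make_record(sig_b, "b")),
                       K = 10L, saturations = rep(5, 8), nets = NULL),
                  class = "odor_database")
  m <- match_database(make_profile(sig_a), db)
  expect_equal(m$verdict, "a")
  expect_equal(m$ranking$label[1], "a")
  expect_equal(m$ranking$n_matched[1], 8)
  # a query matching nothing
  m2 <- match_database(make_profile(matrix(-0.1, 5, 8)), db)
  expect_equal(m2$verdict, "unidentified")
  expect_error(match_database(make_profile(sig_a),
                              structure(list(records = list(), K = 10L),
                                        class = "odor_database")),
               "empty")
})

test_that("success rate is the percentage of correct verdicts", {
  expect_equal(success_rate(c("a", "b"), c("a", "b")), 100)
  expect_equal(success_rate(c(rep("a", 19), "b"), rep("a", 20)), 95)
  set.seed(17)
  truths <- rep(c("a", "b"), 500)
  guesses <- sample(c("a", "b"), 1000, replace = TRUE)
  expect_lt(abs(success_rate(guesses, truths) - 50), 4 * sqrt(0.25 / 1000) * 100)
  expect_error(success_rate(character(0), character(0)), "empty")
  expect_error(success_rate("a", c("a", "b")), "mismatch")
})

test_that("database records store the averaged, denoised class fingerprint", {
  spec <- tiny_pair()[[1]]
  ga_cfg <- ga_config(population_size = 100)
  fr <- generate_event(spec, 150, seed = 1)
  db1 <- build_database(list(x = list(fr)), K = 10, saturations = 5,
                        ga_cfg = ga_cfg, seed = 3)
  # one frame: the signature is that frame's own profile
  expect_equal(db1$records$x$signature$values,
               profile_of_frame(fr, 10, 5)$values, tolerance = 1e-12)
  # duplicated frames: averaging is idempotent
  db2 <- build_database(list(x = list(fr, fr, fr)), K = 10, saturations = 5,
                        ga_cfg = ga_cfg, seed = 3)
  expect_equal(db2$records$x$signature$values, db1$records$x$signature$values,
               tolerance = 1e-12)
  expect_true(all(db1$records$x$elite >= 0 & db1$records$x$elite <= 1))
})

test_that("averaging training frames pulls the signature toward the noiseless profile", {
  noisy <- class_spec("n", amplitude = c(0.4, 0.6, 0.5, 1.2, 1.0, 2.2, 0.8, 3.0),
                      tau = 45, noise_sd = 0.01, drift = 3e-4)
  clean <- class_spec("n", amplitude = c(0.4, 0.6, 0.5, 1.2, 1.0, 2.2, 0.8, 3.0),
                      tau = 45, noise_sd = 0, drift = 3e-4)
  frames <- lapply(1:30, function(s) generate_event(noisy, 200, seed = s))
  ref <- profile_of_frame(generate_event(clean, 200), 10, 5)$values
  db <- build_database(list(n = frames), K = 10, saturations = 5,
                       ga_cfg = ga_config(population_size = 50), seed = 1)
  d_avg <- sqrt(sum((db$records$n$signature$values - ref)^2))
  d_single <- vapply(frames, function(f) {
    sqrt(sum((profile_of_frame(f, 10, 5)$values - ref)^2))
  }, numeric(1))
  expect_true(all(d_avg < d_single))
})

test_that("odor databases round-trip through JSON, including networks", {
  study <- generate_study(tiny_pair(), n_events = 4, duration = 150, seed = 2)
  cfg <- tiny_config(seed = 2)
  db <- run_train(study, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  db_to_json(db, path)
  back <- db_from_json(path)
  expect_identical(names(back$records), names(db$records))
  expect_equal(back$records[[1]]$signature$values, db$records[[1]]$signature$values,
               tolerance = 1e-12)
  expect_equal(back$records[[2]]$elite, db$records[[2]]$elite, tolerance = 1e-12)
  x <- runif(8)
  expect_equal(ann_forward(back$nets[[1]], x), ann_forward(db$nets[[1]], x),
               tolerance = 1e-12)
  # verdicts are unchanged after the round trip
  fr <- study$test[[1]][[1]]
  expect_equal(classify_event(fr, back, cfg)$verdict,
               classify_event(fr, db, cfg)$verdict)
})
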