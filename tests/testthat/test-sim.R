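test_that("noiseless response approaches baseline + amplitude", {
  spec <- quiet_spec(tau = 20)
  fr <- generate_event(spec, duration = 1000)
  plateau <- fr$values[1000, ]
  target <- spec$baseline + spec$amplitude
  expect_true(all(abs(plateau - target) / target < 0.01))
  # and is monotone non-decreasing per channel without noise or drift
  expect_true(all(apply(fr$values, 2, function(v) all(diff(v) >= -1e-12))))
})

test_that("events default to 1000 samples at 1 Hz and are seed-deterministic", {
  spec <- builtin_class_specs()$fish_day3
  fr <- generate_event(spec, seed = 3)
  expect_equal(nrow(fr$values), 1000L)
  expect_identical(fr$times, 0:999)
  expect_identical(fr$values, generate_event(spec, seed = 3)$values)
  expect_false(identical(fr$values, generate_event(spec, seed = 4)$values))
  expect_true(all(fr$values >= 0) &&
                all(sweep(fr$values, 2, spec$saturation, `<=`)))
})

test_that("replicate-averaged noisy events converge to the noiseless curve", {
  spec <- quiet_spec(noise_sd = 0.05, tau = 30)
  clean <- generate_event(quiet_spec(noise_sd = 0, tau = 30), duration = 200)
  n_rep <- 200
  frames <- lapply(seq_len(n_rep), function(s) generate_event(spec, duration = 200, seed = s))
  avg <- average_event(frames)
  tol <- 3 * 0.05 / sqrt(n_rep)
  # interior points: clipping at 0 never binds there for this spec
  expect_lt(max(abs(avg$values - clean$values)), tol * 1.5)
  expect_true(mean(abs(avg$values - clean$values) < tol) > 0.99)
})

test_that("average_event is the elementwise mean with label bookkeeping", {
  spec <- quiet_spec()
  fr <- generate_event(spec, duration = 50, seed = 1)
  expect_equal(average_event(list(fr))$values, fr$values)
  expect_equal(average_event(list(fr))$label, "a")
  # symmetry: frames v and 2k - v average to the constant k
  k <- 2
  f1 <- sensor_frame(matrix(runif(40 * 8, 0, 2), 40, 8))
  f2 <- sensor_frame(2 * k - f1$values)
  expect_equal(average_event(list(f1, f2))$values,
               matrix(k, 40, 8, dimnames = dimnames(f1$values)))
  # mixed labels drop the label
  fb <- generate_event(quiet_spec(label = "b"), duration = 50, seed = 1)
  expect_null(average_event(list(fr, fb))$label)
  expect_error(average_event(list()), "non-empty")
  short <- generate_event(spec, duration = 10, seed = 1)
  expect_error(average_event(list(fr, short)), "length")
})

test_that("averaging reduces noise variance below any single replicate", {
  spec <- quiet_spec(noise_sd = 0.03, tau = 30)
  clean <- generate_event(quiet_spec(noise_sd = 0, tau = 30), duration = 150)
  frames <- lapply(1:10, function(s) generate_event(spec, duration = 150, seed = s))
  avg <- average_event(frames)
  resid_var <- function(f) mean((f$values - clean$values)^2)
  expect_true(all(vapply(frames, resid_var, numeric(1)) > resid_var(avg)))
})

test_that("generate_study splits 50 events per class into 30 train / 20 test", {
  study <- generate_study(tiny_pair(), n_events = 50, train_fraction = 0.6,
                          duration = 20, seed = 5)
  for (label in c("fish_day3", "meat_day3")) {
    expect_length(study$train[[label]], 30L)
    expect_length(study$test[[label]], 20L)
  }
  expect_equal(sum(study$manifest$split == "train"), 60L)
  # seeded rerun is identical
  study2 <- generate_study(tiny_pair(), n_events = 50, train_fraction = 0.6,
                           duration = 20, seed = 5)
  expect_identical(study$manifest, study2$manifest)
  expect_identical(study$train$fish_day3[[1]]$values, study2$train$fish_day3[[1]]$values)
})

test_that("a train fraction of (n-1)/n leaves exactly one test event", {
  study <- generate_study(tiny_pair()[1], n_events = 5, train_fraction = 4 / 5,
                          duration = 20, seed = 1)
  expect_length(study$train$fish_day3, 4L)
  expect_length(study$test$fish_day3, 1L)
})

test_that("simulator inputs are validated", {
  expect_error(generate_event(quiet_spec(), duration = 0), "positive")
  expect_error(class_spec("x", amplitude = 10, tau = 30, saturation = 5), "saturation")
  expect_error(class_spec("x", amplitude = 1, tau = -1), "tau")
  expect_error(class_spec("x", amplitude = 1, tau = 10, noise_sd = -1), "noise_sd")
  expect_error(generate_study(list(), seed = 1), "non-empty")
  expect_error(generate_study(tiny_pair(), n_events = 1), "n_events")
  expect_error(generate_study(tiny_pair(), train_fraction = 1), "train_fraction")
})

test_that("sensor CSV round-trips with the fixed dialect", {
  fr <- generate_event(builtin_class_specs()$meat_fresh, duration = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_csv(fr, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "time,O3,LPG_LNG,NOx,alcohol,smoke,VOC,CO,NH3")
  back <- read_sensor_csv(path)
  expect_equal(back$values, fr$values, tolerance = 1e-12)
  expect_identical(back$label, "meat_fresh")
})
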