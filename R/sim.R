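#' Gas channels of the sensor array
#'
#' Names of the eight gas channels read out by the sensor-array board, in
#' board order. Every [sensor_frame()] carries exactly these channels.
#'
#' @format Character vector of length 8.
#' @export
ENOSE_CHANNELS <- c("O3", "LPG_LNG", "NOx", "alcohol", "smoke", "VOC", "CO", "NH3")

.recycle8 <- function(x, what) {
  if (!is.numeric(x) || !length(x) %in% c(1L, 8L)) {
    stop(sprintf("'%s' must be numeric of length 1 or 8", what), call. = FALSE)
  }
  rep_len(as.numeric(x), 8L)
}

#' Define a substance class for the sensor-array simulator
#'
#' A `class_spec` describes how one odor class (e.g. fish on its third decay
#' day) drives the eight-channel array: each channel rises from its baseline
#' toward `baseline + amplitude` with first-order kinetics of time constant
#' `tau`, on top of a slow linear drift, with additive Gaussian read noise.
#' Responses are clipped to `[0, saturation]` so normalization by the
#' saturation value is always well defined.
#'
#' @param label Class name, e.g. `"fish_day3"`.
#' @param amplitude Per-channel response amplitude in volts (length 1 or 8).
#' @param tau Per-channel rise time constant in seconds (> 0).
#' @param baseline Per-channel baseline voltage (>= 0).
#' @param saturation Per-channel saturation voltage (> 0); also the
#'   normalization constant used downstream.
#' @param drift Slow sensor drift in volts/second (the "natural drift" of
#'   metal-oxide semiconductors; may be 0).
#' @param noise_sd Standard deviation of additive Gaussian noise in volts
#'   (>= 0).
#' @return An object of class `class_spec`.
#' @seealso [generate_event()], [builtin_class_specs()]
#' @export
class_spec <- function(label, amplitude, tau, baseline = 0.4, saturation = 5,
                       drift = 3e-4, noise_sd = 0.002) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("'label' must be a non-empty string", call. = FALSE)
  }
  spec <- list(
    label = label,
    amplitude = .recycle8(amplitude, "amplitude"),
    tau = .recycle8(tau, "tau"),
    baseline = .recycle8(baseline, "baseline"),
    saturation = .recycle8(saturation, "saturation"),
    drift = .recycle8(drift, "drift"),
    noise_sd = .recycle8(noise_sd, "noise_sd")
  )
  if (any(!is.finite(unlist(spec[-1])))) stop("class_spec fields must be finite", call. = FALSE)
  if (any(spec$saturation <= 0)) stop("saturation must be > 0", call. = FALSE)
  if (any(spec$tau <= 0)) stop("tau must be > 0", call. = FALSE)
  if (any(spec$noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(spec$baseline < 0) || any(spec$baseline + spec$amplitude > spec$saturation)) {
    stop("need 0 <= baseline <= baseline + amplitude <= saturation", call. = FALSE)
  }
  class(spec) <- "class_spec"
  spec
}

#' @export
print.class_spec <- function(x, ...) {
  cat("class_spec:", x$label, "\n")
  m <- rbind(amplitude = x$amplitude, tau = x$tau, baseline = x$baseline,
             saturation = x$saturation)
  colnames(m) <- ENOSE_CHANNELS
  print(round(m, 4))
  cat(sprintf("drift %.2g V/s, noise sd %.2g V\n", x$drift[1], x$noise_sd[1]))
  invisible(x)
}

#' Construct a sensor frame
#'
#' A `sensor_frame` is one recording of the eight-channel array: a matrix of
#' non-negative voltages sampled on a uniform 1 Hz grid (time is the 0-based
#' sample index in seconds), with an optional class label.
#'
#' @param values Numeric matrix, one column per channel (8 columns).
#' @param label Optional class label.
#' @return An object of class `sensor_frame` with elements `times`, `values`
#'   (colnames [ENOSE_CHANNELS]), and `label`.
#' @export
sensor_frame <- function(values, label = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 8L) stop("a sensor_frame has exactly 8 channels", call. = FALSE)
  if (nrow(values) < 1L) stop("empty sensor_frame", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("sensor values must be finite and >= 0", call. = FALSE)
  }
  colnames(values) <- ENOSE_CHANNELS
  structure(list(times = seq_len(nrow(values)) - 1L, values = values, label = label),
            class = "sensor_frame")
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("sensor_frame: %d samples x 8 channels @ 1 Hz%s\n",
              nrow(x$values),
              if (is.null(x$label)) "" else paste0(", label '", x$label, "'")))
  invisible(x)
}

#' Simulate one sensor-array event
#'
#' Generates a single odor-exposure recording: channel \eqn{c} at time
#' \eqn{t} equals
#' \deqn{b_c + A_c (1 - e^{-t/\tau_c}) + \mathrm{drift}\cdot t + \epsilon,}
#' with \eqn{\epsilon \sim N(0, \mathrm{sd}^2)}, clipped to
#' \eqn{[0, s_c]}. Identical seeds give bitwise-identical frames.
#'
#' @param spec A [class_spec()].
#' @param duration Number of 1 Hz samples (default 1000, one standard event).
#' @param seed Optional integer seed for the noise.
#' @return A labelled [sensor_frame()].
#' @export
generate_event <- function(spec, duration = 1000, seed = NULL) {
  if (!inherits(spec, "class_spec")) stop("'spec' must be a class_spec", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration < 1) {
    stop("'duration' must be a positive number of samples", call. = FALSE)
  }
  duration <- as.integer(duration)
  if (!is.null(seed)) set.seed(as.integer(seed))
  t <- seq_len(duration) - 1L
  vals <- matrix(0, duration, 8L)
  for (c in 1:8) {
    mu <- spec$baseline[c] + spec$amplitude[c] * (1 - exp(-t / spec$tau[c])) +
      spec$drift[c] * t
    x <- mu + if (spec$noise_sd[c] > 0) stats::rnorm(duration, 0, spec$noise_sd[c]) else 0
    vals[, c] <- pmin(pmax(x, 0), spec$saturation[c])
  }
  sensor_frame(vals, label = spec$label)
}

#' Average sensor frames element-wise
#'
#' Per-time, per-channel mean of repeated recordings, used to build the
#' low-noise class fingerprint from the training replicates. The label is
#' kept only when it is unanimous.
#'
#' @param frames Non-empty list of [sensor_frame()]s of equal length.
#' @return A [sensor_frame()].
#' @export
average_event <- function(frames) {
  if (!is.list(frames) || length(frames) == 0L) stop("'frames' must be a non-empty list", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "sensor_frame"))) {
    stop("all elements must be sensor_frames", call. = FALSE)
  }
  n <- nrow(frames[[1L]]$values)
  if (!all(vapply(frames, function(f) nrow(f$values) == n, logical(1)))) {
    stop("frames differ in length", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(frames, `[[`, "values")) / length(frames)
  labs <- unique(vapply(frames, function(f) if (is.null(f$label)) NA_character_ else f$label,
                        character(1)))
  sensor_frame(acc, label = if (length(labs) == 1L && !is.na(labs)) labs else NULL)
}

.derive_seed <- function(seed, offset) {
  # keep derived seeds inside 32-bit integer range
  as.integer((as.numeric(seed) %% 65011) * 33013 + offset) %% 2147483646L + 1L
}

#' Generate a full synthetic study with train/test split
#'
#' Simulates `n_events` repeated events per class and splits them into a
#' training and a held-out test set (default 50 events per class, split
#' 30/20). The split is a seeded permutation, so the same seed always
#' reproduces the same study.
#'
#' @param specs Non-empty list of [class_spec()]s.
#' @param n_events Events per class (>= 2).
#' @param train_fraction Fraction of events used for training (0 < f < 1).
#' @param duration Samples per event.
#' @param seed Integer seed; all per-event seeds derive from it.
#' @return A list with `train` and `test` (named lists of sensor_frame lists,
#'   one entry per class label) and `manifest`, a data.frame with one row per
#'   event (`event_id`, `label`, `split`, `seed`).
#' @export
generate_study <- function(specs, n_events = 50, train_fraction = 0.6,
                           duration = 1000, seed = 1) {
  if (!is.list(specs) || length(specs) == 0L) stop("'specs' must be a non-empty list", call. = FALSE)
  if (!all(vapply(specs, inherits, logical(1), "class_spec"))) {
    stop("all specs must be class_spec objects", call. = FALSE)
  }
  if (n_events < 2) stop("'n_events' must be >= 2", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) stop("'train_fraction' must be in (0,1)", call. = FALSE)
  n_events <- as.integer(n_events)
  n_train <- max(1L, min(n_events - 1L, as.integer(floor(train_fraction * n_events))))

  train <- list(); test <- list(); manifest <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    ev_seeds <- vapply(seq_len(n_events), function(j) .derive_seed(seed, i * 1000L + j),
                       integer(1))
    frames <- lapply(ev_seeds, function(s) generate_event(spec, duration, seed = s))
    set.seed(.derive_seed(seed, i * 1000L))
    perm <- sample.int(n_events)
    idx_train <- sort(perm[seq_len(n_train)])
    idx_test <- sort(perm[-seq_len(n_train)])
    train[[spec$label]] <- frames[idx_train]
    test[[spec$label]] <- frames[idx_test]
    split <- rep("test", n_events); split[idx_train] <- "train"
    manifest[[i]] <- data.frame(
      event_id = sprintf("%s_%03d", spec$label, seq_len(n_events)),
      label = spec$label, split = split, seed = ev_seeds,
      stringsAsFactors = FALSE)
  }
  list(train = train, test = test, manifest = do.call(rbind, manifest))
}

#' Built-in substance classes
#'
#' Four illustrative odor classes modelled on decaying fish and meat: fresh
#' samples give small responses; decayed samples emit amines and volatile
#' organics, driving the NH3, VOC and smoke channels hard (fish strongly on
#' NH3, meat more broadly on VOC/smoke). Amplitudes and time constants are
#' hand-chosen illustrations of such fingerprints, not fits to any
#' measurement.
#'
#' @param noise_sd Gaussian read-noise standard deviation in volts applied to
#'   every class (default 0.002 V, i.e. millivolt-scale ADC noise).
#' @return Named list of [class_spec()]s:
#'   `fish_fresh`, `fish_day3`, `meat_fresh`, `meat_day3`.
#' @export
builtin_class_specs <- function(noise_sd = 0.002) {
  list(
    fish_fresh = class_spec("fish_fresh",
      amplitude = c(0.30, 0.40, 0.30, 0.50, 0.40, 0.80, 0.40, 0.90),
      tau = 60, noise_sd = noise_sd),
    fish_day3 = class_spec("fish_day3",
      amplitude = c(0.40, 0.60, 0.50, 1.20, 1.00, 2.20, 0.80, 3.00),
      tau = 45, noise_sd = noise_sd),
    meat_fresh = class_spec("meat_fresh",
      amplitude = c(0.30, 0.50, 0.40, 0.60, 0.50, 1.00, 0.50, 0.50),
      tau = 70, noise_sd = noise_sd),
    meat_day3 = class_spec("meat_day3",
      amplitude = c(0.50, 0.90, 0.70, 1.50, 1.30, 2.60, 1.20, 1.60),
      tau = 55, noise_sd = noise_sd)
  )
}

#' Write / read a sensor frame as CSV
#'
#' The CSV dialect is fixed: header
#' `time,O3,LPG_LNG,NOx,alcohol,smoke,VOC,CO,NH3`, one row per second,
#' `.` decimal, UTF-8. The label (if any) is stored in a JSON sidecar at
#' `<path>.json`.
#'
#' @param frame A [sensor_frame()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(frame, path) {
  if (!inherits(frame, "sensor_frame")) stop("'frame' must be a sensor_frame", call. = FALSE)
  df <- data.frame(time = frame$times, frame$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(frame$label)) {
    jsonlite::write_json(list(label = frame$label), paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), c("time", ENOSE_CHANNELS))) {
    stop("unexpected CSV header; expected time,", paste(ENOSE_CHANNELS, collapse = ","),
         call. = FALSE)
  }
  label <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) label <- jsonlite::read_json(sidecar)$label
  sensor_frame(as.matrix(df[, ENOSE_CHANNELS]), label = label)
}
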