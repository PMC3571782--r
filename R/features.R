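#' Windowed gradient of a smoothed series
#'
#' The gradient feature is the rate of change of the smoothed, normalized
#' signal, evaluated whenever the time `t` (0-based, seconds at 1 Hz) is a
#' positive multiple of the window `K`:
#' \deqn{T(t) = (S(t) - S(0)) / t \quad (t \le K),\qquad
#'       T(t) = (S(t) - S(t-K)) / K \quad (t > K).}
#' The two branches coincide at `t = K`, the first point of the grid; `t = 0`
#' is excluded (its first branch divides by zero).
#'
#' @param smoothed Numeric vector: a smoothed (and normally normalized)
#'   series, e.g. from [smma()] then [normalize_series()].
#' @param K Window size in samples; the series must be longer than `K`.
#' @return A data.frame with columns `t` (evaluation times `K, 2K, ...`) and
#'   `value` (gradients, per second).
#' @export
gradient_series <- function(smoothed, K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("'K' must be >= 1", call. = FALSE)
  K <- as.integer(K)
  n <- length(smoothed)
  if (n <= K) stop("series must be longer than K samples", call. = FALSE)
  if (any(!is.finite(smoothed))) stop("series must be finite", call. = FALSE)
  t_eval <- seq.int(K, n - 1L, by = K)
  # S(t) = smoothed[t + 1] on the 0-based grid; both branches reduce to a
  # difference over one window of length K
  value <- (smoothed[t_eval + 1L] - smoothed[t_eval - K + 1L]) / K
  data.frame(t = t_eval, value = value)
}

#' Gradient profile of a sensor frame
#'
#' Runs the preprocessing chain per channel — [smma()] smoothing, saturation
#' normalization, then [gradient_series()] — giving the eight-channel
#' gradient signature on the shared grid `t = K, 2K, ...`. This signature is
#' what the odor database stores and matches.
#'
#' @param frame A [sensor_frame()].
#' @param K Window size in samples.
#' @param saturations Per-channel saturation voltages (length 1 or 8).
#' @param role `"input"` for reference/training data, `"test"` for query
#'   data. Bookkeeping only; the computation is identical.
#' @return An object of class `gradient_profile`: list with `t` (grid),
#'   `values` (times x 8 gradient matrix), `K`, `role`, `label`.
#' @export
profile_of_frame <- function(frame, K, saturations, role = c("input", "test")) {
  if (!inherits(frame, "sensor_frame")) stop("'frame' must be a sensor_frame", call. = FALSE)
  role <- match.arg(role)
  sm <- smma(frame$values, K)
  nm <- normalize_series(sm, rep_len(saturations, 8L))
  grads <- apply(nm, 2L, function(col) gradient_series(col, K)$value)
  t_eval <- gradient_series(nm[, 1L], K)$t
  grads <- matrix(grads, nrow = length(t_eval), ncol = 8L,
                  dimnames = list(NULL, ENOSE_CHANNELS))
  structure(list(t = t_eval, values = grads, K = as.integer(K), role = role,
                 label = frame$label),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("gradient_profile: %d epochs (t = %d..%d, K = %d), role '%s'%s\n",
              length(x$t), x$t[1], x$t[length(x$t)], x$K, x$role,
              if (is.null(x$label)) "" else paste0(", label '", x$label, "'")))
  invisible(x)
}

#' Serialize a gradient profile to JSON
#'
#' @param profile A [profile_of_frame()] result.
#' @param path Output JSON path.
#' @return `path` invisibly; `profile_from_json()` returns the profile.
#' @export
profile_to_json <- function(profile, path) {
  stopifnot(inherits(profile, "gradient_profile"))
  obj <- list(K = profile$K, role = profile$role, label = profile$label,
              t = profile$t,
              channels = lapply(as.data.frame(profile$values), identity))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname profile_to_json
#' @export
profile_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- do.call(cbind, obj$channels[ENOSE_CHANNELS])
  structure(list(t = as.integer(obj$t), values = vals, K = as.integer(obj$K),
                 role = obj$role, label = obj$label),
            class = "gradient_profile")
}
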