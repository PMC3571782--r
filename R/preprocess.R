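#' Smoothed moving average (SMMA)
#'
#' Causal windowed-mean filter used to denoise the raw sensor stream:
#' `out[t] = mean(x[max(1, t-K+1) .. t])` (1-based indices). The window is
#' trailing, so the filter is online — it drops the oldest sample and adds
#' the newest — and partial at the start, which keeps the output the same
#' length as the input without peeking at future samples.
#'
#' @param x Numeric vector, or matrix with one column per channel.
#' @param K Window size in samples (>= 1). K also sets the gradient grid of
#'   [gradient_series()] and the fitness scale of [ga_fitness()].
#' @return Filtered series, same shape as `x`.
#' @examples
#' smma(c(1, 2, 3, 4, 5), K = 3)  # 1.0 1.5 2.0 3.0 4.0
#' @export
smma <- function(x, K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("'K' must be >= 1", call. = FALSE)
  K <- as.integer(K)
  if (is.matrix(x)) {
    out <- apply(x, 2L, smma, K = K)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  if (n == 0L) stop("empty series", call. = FALSE)
  if (any(!is.finite(x))) stop("series must be finite", call. = FALSE)
  cs <- cumsum(x)
  out <- numeric(n)
  head_n <- seq_len(min(K, n))
  out[head_n] <- cs[head_n] / head_n
  if (n > K) {
    idx <- (K + 1L):n
    out[idx] <- (cs[idx] - cs[idx - K]) / K
  }
  out
}

#' Normalize a series by its saturation value
#'
#' Maps raw voltages into `[0, 1]` by dividing by the per-channel saturation
#' value. A reading above saturation signals a mis-configured saturation and
#' is an error rather than silently clipped.
#'
#' @param x Numeric vector, or matrix with one column per channel.
#' @param saturation Positive saturation voltage; for a matrix, length 1 or
#'   one value per column.
#' @return Unitless series in `[0, 1]`, same shape as `x`.
#' @seealso [denormalize_series()] for the inverse map.
#' @export
normalize_series <- function(x, saturation) {
  if (any(!is.finite(saturation)) || any(saturation <= 0)) {
    stop("'saturation' must be positive and finite", call. = FALSE)
  }
  if (is.matrix(x)) {
    sat <- rep_len(saturation, ncol(x))
    if (any(x < 0) || any(sweep(x, 2L, sat, `>`))) {
      stop("values must lie in [0, saturation]", call. = FALSE)
    }
    return(sweep(x, 2L, sat, `/`))
  }
  if (length(saturation) != 1L) stop("vector input takes a scalar saturation", call. = FALSE)
  if (any(x < 0) || any(x > saturation)) stop("values must lie in [0, saturation]", call. = FALSE)
  x / saturation
}

#' @rdname normalize_series
#' @param x_norm Normalized series as returned by [normalize_series()].
#' @export
denormalize_series <- function(x_norm, saturation) {
  if (any(!is.finite(saturation)) || any(saturation <= 0)) {
    stop("'saturation' must be positive and finite", call. = FALSE)
  }
  if (is.matrix(x_norm)) return(sweep(x_norm, 2L, rep_len(saturation, ncol(x_norm)), `*`))
  x_norm * saturation
}
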