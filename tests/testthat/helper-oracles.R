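# Independent brute-force oracles, written as plain loops so they share no
# code path with the package implementations they check.

oracle_smma <- function(x, K) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    lo <- max(1L, t - K + 1L)
    out[t] <- mean(x[lo:t])
  }
  out
}

oracle_gradient <- function(smoothed, K) {
  # two-branch formula evaluated literally at each multiple of K (0-based t)
  n <- length(smoothed)
  S <- function(t) smoothed[t + 1L]
  t_eval <- seq.int(K, n - 1L, by = K)
  vals <- numeric(length(t_eval))
  for (i in seq_along(t_eval)) {
    t <- t_eval[i]
    vals[i] <- if (t <= K) (S(t) - S(0)) / t else (S(t) - S(t - K)) / K
  }
  list(t = t_eval, value = vals)
}

oracle_fitness <- function(x, K) {
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- x[i] + K * abs(sin(32 * x[i]))
  out
}

oracle_target_value <- function(Y, P) {
  s <- 0
  for (i in seq_along(Y)) s <- s + abs(Y[i] - P[i]) / max(Y)
  s / length(Y)
}

# central finite differences of the batch error E = 0.5 * sum((P - Y)^2)
oracle_ann_error <- function(net, X, y) {
  p <- enose::ann_forward(net, as.matrix(X))
  0.5 * sum((p - y)^2)
}

oracle_fd_gradients <- function(net, X, y, h = 1e-6) {
  num <- function(get, set) {
    w <- get(net)
    g <- array(0, dim = dim(as.matrix(w)))
    for (i in seq_along(w)) {
      np <- net; nm <- net
      wp <- w; wp[i] <- wp[i] + h
      wm <- w; wm[i] <- wm[i] - h
      np <- set(np, wp); nm <- set(nm, wm)
      g[i] <- (oracle_ann_error(np, X, y) - oracle_ann_error(nm, X, y)) / (2 * h)
    }
    g
  }
  list(
    dW1 = num(function(n) n$W1, function(n, w) { n$W1 <- w; n }),
    db1 = as.vector(num(function(n) n$b1, function(n, w) { n$b1 <- as.vector(w); n })),
    dW2 = num(function(n) n$W2, function(n, w) { n$W2 <- w; n }),
    db2 = as.vector(num(function(n) n$b2, function(n, w) { n$b2 <- as.vector(w); n }))
  )
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-12, max(abs(b)))
}
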