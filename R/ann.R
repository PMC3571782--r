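#' Neural-network training configuration
#'
#' Hyperparameters of the backpropagation stage. The defaults are the
#' method's standard operating point: learning rate 0.01, momentum 0.2,
#' learning goal 0.0002.
#'
#' @param learning_rate Step size (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param goal Stopping error: training stops once the epoch error falls to
#'   or below this value.
#' @param max_epochs Upper bound on training epochs.
#' @param stop_metric Which epoch error the goal applies to: `"mse"` (mean
#'   squared error, the default) or `"target_d"` (the normalized
#'   absolute-deviation target value, see [target_value()]). Both are logged
#'   either way.
#' @param output_threshold Decision threshold used by [ann_stage()].
#' @param seed Optional RNG seed for weight initialization.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.2, goal = 2e-4,
                         max_epochs = 50000, stop_metric = c("mse", "target_d"),
                         output_threshold = 0.5, seed = NULL) {
  stop_metric <- match.arg(stop_metric)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0,1)", call. = FALSE)
  if (goal <= 0) stop("goal must be > 0", call. = FALSE)
  structure(list(learning_rate = learning_rate, momentum = momentum, goal = goal,
                 max_epochs = as.integer(max_epochs), stop_metric = stop_metric,
                 output_threshold = output_threshold, seed = seed),
            class = "train_config")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize a feedforward network
#'
#' Builds an `input -> hidden -> 1` fully connected network with logistic
#' sigmoid activations. Weights and biases are drawn uniformly on
#' `[-0.5, 0.5]`.
#'
#' @param input_size Number of inputs (default 8, one per sensor channel).
#' @param hidden_size Hidden units (>= 1; default 8).
#' @param seed Optional integer seed.
#' @return An object of class `ann_network` with weight matrices `W1`
#'   (input x hidden), `W2` (hidden x 1), biases `b1`, `b2`, and a `trained`
#'   flag.
#' @export
init_network <- function(input_size = 8, hidden_size = 8, seed = NULL) {
  if (hidden_size < 1) stop("hidden_size must be >= 1", call. = FALSE)
  if (input_size < 1) stop("input_size must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  u <- function(n) stats::runif(n, -0.5, 0.5)
  structure(list(
    input_size = as.integer(input_size), hidden_size = as.integer(hidden_size),
    W1 = matrix(u(input_size * hidden_size), input_size, hidden_size),
    b1 = u(hidden_size),
    W2 = matrix(u(hidden_size), hidden_size, 1L),
    b2 = u(1L),
    trained = FALSE), class = "ann_network")
}

.ann_pass <- function(net, X) {
  A1 <- .sigmoid(sweep(X %*% net$W1, 2L, net$b1, `+`))
  out <- .sigmoid(A1 %*% net$W2 + net$b2[1L])
  list(hidden = A1, output = out)
}

#' Forward pass
#'
#' Sigmoid feedforward evaluation; outputs are strictly inside `(0, 1)`.
#'
#' @param net An [init_network()] model.
#' @param x Input vector of length `input_size`, or a matrix with one sample
#'   per row.
#' @return Scalar output, or a vector with one output per row of `x`.
#' @export
ann_forward <- function(net, x) {
  stopifnot(inherits(net, "ann_network"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != net$input_size) stop("input length must equal input_size", call. = FALSE)
  out <- .ann_pass(net, X)$output
  if (is.matrix(x)) as.vector(out) else out[1L, 1L]
}

#' Normalized absolute-deviation target value
#'
#' The learning-evaluation statistic
#' \deqn{d = \frac{1}{m} \sum_{i=1}^{m} \frac{|Y_i - P_i|}{Y_{max}},}
#' where `Y` are the outputs (targets), `P` the predicted values, and
#' `Y_max = max(Y)` the normalizer. `d` is zero iff the predictions equal the
#' targets.
#'
#' @param Y Numeric vector of outputs/targets (max must be positive).
#' @param P Numeric vector of predictions, same length.
#' @return Scalar `d >= 0`.
#' @export
target_value <- function(Y, P) {
  if (length(Y) != length(P)) stop("'Y' and 'P' must have equal length", call. = FALSE)
  if (length(Y) < 1L) stop("need at least one value", call. = FALSE)
  y_max <- max(Y)
  if (y_max == 0) stop("max(Y) is zero: degenerate normalizer", call. = FALSE)
  (sum(abs(Y - P)) / y_max) / length(Y)
}

#' Backpropagation gradients
#'
#' Gradients of the batch error \eqn{E = \tfrac12 \sum_i (P_i - Y_i)^2} with
#' respect to all weights and biases, computed by the chain rule through the
#' sigmoid layers. Exposed so the analytic gradients can be checked against
#' finite differences.
#'
#' @param net An [init_network()] model.
#' @param X Sample matrix (rows) of width `input_size`.
#' @param y Target vector in `(0,1)`, one per row of `X`.
#' @return List `dW1`, `db1`, `dW2`, `db2` matching the network's shapes.
#' @export
ann_gradients <- function(net, X, y) {
  stopifnot(inherits(net, "ann_network"))
  X <- as.matrix(X)
  fw <- .ann_pass(net, X)
  err <- fw$output - y
  d2 <- err * fw$output * (1 - fw$output)
  d1 <- (d2 %*% t(net$W2)) * fw$hidden * (1 - fw$hidden)
  list(dW1 = t(X) %*% d1, db1 = colSums(d1),
       dW2 = t(fw$hidden) %*% d2, db2 = sum(d2))
}

#' Train a network by backpropagation with momentum
#'
#' Full-batch gradient descent on \eqn{E = \tfrac12 \sum (P - Y)^2} with
#' momentum: `dw <- -lr * dE/dw + momentum * dw_prev`. Each epoch the mean
#' squared error and the target value `d` ([target_value()]) are recorded;
#' training stops when the configured stopping metric reaches the learning
#' goal (checked before the first update, so a dataset the net already fits
#' stops at epoch 0) or at `max_epochs`.
#'
#' @param net An [init_network()] model.
#' @param X Sample matrix, one row per training pair.
#' @param y Targets in `(0, 1)`.
#' @param config A [train_config()].
#' @return List with `net` (trained, `trained = TRUE`), `history`
#'   (data.frame `epoch`, `mse`, `target_d`), `converged`, `epochs`.
#' @export
ann_train <- function(net, X, y, config = train_config()) {
  stopifnot(inherits(net, "ann_network"), inherits(config, "train_config"))
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("empty training set", call. = FALSE)
  if (length(y) != nrow(X)) stop("one target per sample required", call. = FALSE)
  if (any(y <= 0) || any(y >= 1)) stop("targets must lie strictly in (0,1)", call. = FALSE)

  lr <- config$learning_rate; mom <- config$momentum
  vW1 <- net$W1 * 0; vb1 <- net$b1 * 0; vW2 <- net$W2 * 0; vb2 <- 0
  hist_ep <- integer(); hist_mse <- numeric(); hist_d <- numeric()
  epoch <- 0L
  converged <- FALSE
  repeat {
    fw <- .ann_pass(net, X)
    err <- as.vector(fw$output) - y
    mse <- mean(err^2)
    d <- target_value(y, as.vector(fw$output))
    hist_ep <- c(hist_ep, epoch); hist_mse <- c(hist_mse, mse); hist_d <- c(hist_d, d)
    metric <- if (config$stop_metric == "mse") mse else d
    if (metric <= config$goal) { converged <- TRUE; break }
    if (epoch >= config$max_epochs) break
    d2 <- matrix(err * as.vector(fw$output) * (1 - as.vector(fw$output)), ncol = 1L)
    d1 <- (d2 %*% t(net$W2)) * fw$hidden * (1 - fw$hidden)
    vW1 <- -lr * (t(X) %*% d1) + mom * vW1
    vb1 <- -lr * colSums(d1) + mom * vb1
    vW2 <- -lr * (t(fw$hidden) %*% d2) + mom * vW2
    vb2 <- -lr * sum(d2) + mom * vb2
    net$W1 <- net$W1 + vW1; net$b1 <- net$b1 + vb1
    net$W2 <- net$W2 + vW2; net$b2 <- net$b2 + vb2
    epoch <- epoch + 1L
  }
  net$trained <- TRUE
  list(net = net,
       history = data.frame(epoch = hist_ep, mse = hist_mse, target_d = hist_d),
       converged = converged, epochs = epoch)
}

#' Score a denoised feature vector and decide whether to proceed
#'
#' Runs the trained network on the GA-denoised feature vector and compares
#' the score with the output threshold: at or above the threshold the
#' pipeline proceeds to database evaluation, below it the network should be
#' rebuilt/retrained.
#'
#' @param features Numeric 8-vector of (denoised) features in `[0,1]`.
#' @param net A trained [init_network()] model.
#' @param threshold Output threshold (default 0.5).
#' @return List with `score`, `proceed`, `retrain`.
#' @export
ann_stage <- function(features, net, threshold = 0.5) {
  stopifnot(inherits(net, "ann_network"))
  if (!isTRUE(net$trained)) stop("network has not been trained", call. = FALSE)
  score <- ann_forward(net, as.numeric(features))
  list(score = score, proceed = score >= threshold, retrain = score < threshold)
}

#' Serialize a network to JSON
#'
#' @param net An [init_network()] model.
#' @param path Output JSON path.
#' @return `path` invisibly; `ann_from_json()` returns the network.
#' @export
ann_to_json <- function(net, path) {
  stopifnot(inherits(net, "ann_network"))
  obj <- list(input_size = net$input_size, hidden_size = net$hidden_size,
              W1 = net$W1, b1 = net$b1, W2 = as.vector(net$W2), b2 = net$b2,
              trained = net$trained)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname ann_to_json
#' @export
ann_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(input_size = as.integer(o$input_size),
                 hidden_size = as.integer(o$hidden_size),
                 W1 = matrix(o$W1, o$input_size, o$hidden_size, byrow = FALSE),
                 b1 = as.numeric(o$b1),
                 W2 = matrix(o$W2, o$hidden_size, 1L),
                 b2 = as.numeric(o$b2),
                 trained = isTRUE(o$trained)), class = "ann_network")
}
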