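#' Principal component analysis of a feature matrix
#'
#' Covariance-mode PCA (optionally correlation-mode) of the per-event
#' feature matrix, used as a visual diagnostic of class separation in the
#' training data. Components carry a fixed sign convention: the
#' largest-magnitude element of each loading vector is positive.
#'
#' @param X Numeric matrix, samples x features (>= 2 samples, no missing
#'   values).
#' @param mode `"covariance"` (default) or `"correlation"` (standardized
#'   features).
#' @return An object of class `pca_result`: `components` (orthonormal
#'   loadings, one column per component), `eigenvalues` (descending),
#'   `scores` (projected coordinates), `center`, `scale`, `mode`.
#' @export
pca_fit <- function(X, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(X))) stop("X must not contain missing values", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = (mode == "correlation"))
  comp <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) {
      comp[, j] <- -comp[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(components = comp, eigenvalues = pc$sdev^2, scores = scores,
                 center = pc$center,
                 scale = if (mode == "correlation") pc$scale else NULL,
                 mode = mode),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ev <- x$eigenvalues
  cat(sprintf("pca_result (%s mode): %d components\n", x$mode, length(ev)))
  cat("eigenvalues:", paste(signif(ev, 4), collapse = ", "), "\n")
  cat(sprintf("variance explained by PC1: %.1f%%\n", 100 * ev[1] / sum(ev)))
  invisible(x)
}

#' Scree summary: eigenvalues and dominance ratio
#'
#' Descending eigenvalues of the feature covariance (or correlation) matrix
#' together with the dominance ratio `lambda1 / lambda2` — how much stronger
#' the leading response axis is than the second. The ratio is `Inf` for
#' numerically rank-1 data.
#'
#' @inheritParams pca_fit
#' @return List with `eigenvalues` and `dominance_ratio`.
#' @export
scree <- function(X, mode = c("covariance", "correlation")) {
  fit <- pca_fit(X, mode = match.arg(mode))
  ev <- fit$eigenvalues
  dom <- if (length(ev) < 2L || ev[2L] <= 1e-12 * ev[1L]) Inf else ev[1L] / ev[2L]
  list(eigenvalues = ev, dominance_ratio = dom)
}

#' Diagnostic PCA plots
#'
#' Convenience base-graphics plots: an eigenvalue bar chart and a 2-D score
#' scatter colored by class. When `file` is given the plot is written as PNG.
#'
#' @param fit A [pca_fit()] result.
#' @param file Optional PNG output path.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_scree <- function(fit, file = NULL) {
  stopifnot(inherits(fit, "pca_result"))
  if (!is.null(file)) grDevices::png(file, width = 700, height = 500)
  graphics::barplot(fit$eigenvalues, names.arg = seq_along(fit$eigenvalues),
                    xlab = "component", ylab = "eigenvalue",
                    main = "PCA eigenvalues")
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

#' @rdname plot_scree
#' @param labels Optional per-sample class labels for coloring the scores.
#' @export
plot_scores <- function(fit, labels = NULL, file = NULL) {
  stopifnot(inherits(fit, "pca_result"))
  if (!is.null(file)) grDevices::png(file, width = 700, height = 500)
  col <- if (is.null(labels)) 1L else as.integer(factor(labels))
  graphics::plot(fit$scores[, 1L], fit$scores[, 2L], col = col, pch = 19,
                 xlab = "PC1", ylab = "PC2", main = "PCA scores")
  if (!is.null(labels)) {
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))), pch = 19)
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

#' Export eigenvalues and scores to CSV
#'
#' @param fit A [pca_fit()] result.
#' @param scores_path,eigen_path Output CSV paths (either may be `NULL`).
#' @param labels Optional per-sample labels added to the scores CSV.
#' @return Invisibly, the paths written.
#' @export
pca_to_csv <- function(fit, scores_path = NULL, eigen_path = NULL, labels = NULL) {
  stopifnot(inherits(fit, "pca_result"))
  if (!is.null(eigen_path)) {
    utils::write.csv(data.frame(component = seq_along(fit$eigenvalues),
                                eigenvalue = fit$eigenvalues),
                     eigen_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(scores_path)) {
    df <- as.data.frame(fit$scores)
    if (!is.null(labels)) df <- cbind(label = labels, df)
    utils::write.csv(df, scores_path, row.names = FALSE, quote = TRUE)
  }
  invisible(c(scores_path, eigen_path))
}
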