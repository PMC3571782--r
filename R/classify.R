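#' Similarity between two gradient values
#'
#' Per-channel, per-epoch similarity used by the matching rule. Gradients of
#' opposite sign have similarity 0 ("different pattern"); gradients of the
#' same sign score by relative closeness,
#' `1 - |q - r| / max(|q|, |r|)`, which lies in `[0, 1]`. Magnitudes below
#' `eps` count as sign 0 and match only sign 0 (two such flat gradients score
#' 1).
#'
#' @param g_query,g_ref Gradient values (vectorized, recycled).
#' @param eps Flat-gradient tolerance in normalized units.
#' @return Similarities in `[0, 1]`.
#' @examples
#' channel_similarity(0.08, 0.10)   # 0.8
#' channel_similarity(0.1, -0.1)    # 0: opposite pattern
#' @export
channel_similarity <- function(g_query, g_ref, eps = 1e-6) {
  if (any(!is.finite(g_query)) || any(!is.finite(g_ref))) {
    stop("gradients must be finite", call. = FALSE)
  }
  n <- max(length(g_query), length(g_ref))
  q <- rep_len(g_query, n); r <- rep_len(g_ref, n)
  sq <- sign(q) * (abs(q) >= eps)
  sr <- sign(r) * (abs(r) >= eps)
  out <- numeric(n)
  both_zero <- sq == 0 & sr == 0
  same <- sq == sr & !both_zero
  out[both_zero] <- 1
  out[same] <- 1 - abs(q[same] - r[same]) / pmax(abs(q[same]), abs(r[same]))
  out
}

#' Build a reference record from training frames
#'
#' Averages the class's training frames into a low-noise fingerprint, stores
#' its gradient profile as the class signature, and attaches the GA-elite
#' denoised feature vector used by the neural stage.
#'
#' @param frames List of training [sensor_frame()]s of one class.
#' @param label Class label.
#' @param K Window size.
#' @param saturations Per-channel saturations.
#' @param ga_cfg [ga_config()] for the denoising stage.
#' @return An object of class `reference_record`: `label`, `signature`
#'   (a [profile_of_frame()] gradient profile), `elite` (8-vector), and
#'   `provenance` (training event indices).
#' @export
reference_record <- function(frames, label, K, saturations, ga_cfg = ga_config()) {
  if (length(frames) == 0L) stop("a class needs at least one training frame", call. = FALSE)
  avg <- average_event(frames)
  avg$label <- label
  structure(list(
    label = label,
    signature = profile_of_frame(avg, K, saturations, role = "input"),
    elite = ga_denoise(avg, K, saturations, ga_cfg),
    provenance = seq_along(frames)), class = "reference_record")
}

#' Build the odor-reference database
#'
#' One [reference_record()] per class from its training frames. Per-class GA
#' seeds are derived from `seed` so the build is reproducible.
#'
#' @param frames_by_class Named list: class label -> list of training frames.
#' @param K Window size.
#' @param saturations Per-channel saturations.
#' @param ga_cfg [ga_config()] template for the denoising stage.
#' @param seed Integer seed.
#' @return An object of class `odor_database`: `records` (named list),
#'   `K`, `saturations`, and `nets` (`NULL` until [train_database_nets()]).
#' @export
build_database <- function(frames_by_class, K, saturations,
                           ga_cfg = ga_config(), seed = 1) {
  if (length(frames_by_class) == 0L || is.null(names(frames_by_class))) {
    stop("'frames_by_class' must be a named list of frame lists", call. = FALSE)
  }
  records <- list()
  for (i in seq_along(frames_by_class)) {
    label <- names(frames_by_class)[i]
    cfg <- ga_cfg
    cfg$seed <- .derive_seed(seed, 5000L + i)
    records[[label]] <- reference_record(frames_by_class[[i]], label, K, saturations, cfg)
  }
  structure(list(records = records, K = as.integer(K),
                 saturations = rep_len(saturations, 8L), nets = NULL),
            class = "odor_database")
}

#' @export
print.odor_database <- function(x, ...) {
  cat(sprintf("odor_database: %d classes (K = %d)%s\n", length(x$records), x$K,
              if (is.null(x$nets)) "" else ", with trained networks"))
  for (r in x$records) cat(" -", r$label, "\n")
  invisible(x)
}

#' Match a query profile against one reference record
#'
#' A channel matches when its similarity ([channel_similarity()]) to the
#' stored signature is at least `sim_threshold` at **every** shared epoch;
#' identification succeeds when at least `min_channels` of the 8 channels
#' match.
#'
#' @param query A [profile_of_frame()] gradient profile.
#' @param record A [reference_record()].
#' @param sim_threshold Per-epoch similarity threshold (default 0.80).
#' @param min_channels Channels required for success (default 6).
#' @param strict_inequality If `TRUE`, require similarity strictly above the
#'   threshold.
#' @param eps Flat-gradient tolerance.
#' @return An object of class `classification_result`: `label`,
#'   `similarity` (per-channel mean over epochs), `channel_match` (logical
#'   8-vector), `n_matched`, `success`, `mean_similarity`.
#' @export
match_record <- function(query, record, sim_threshold = 0.80, min_channels = 6,
                         strict_inequality = FALSE, eps = 1e-6) {
  stopifnot(inherits(query, "gradient_profile"), inherits(record, "reference_record"))
  sig <- record$signature
  if (query$K != sig$K) stop("window size mismatch between query and record", call. = FALSE)
  shared <- intersect(query$t, sig$t)
  if (length(shared) == 0L) stop("no shared epochs between query and record", call. = FALSE)
  qi <- match(shared, query$t); ri <- match(shared, sig$t)
  sims <- matrix(0, length(shared), 8L, dimnames = list(NULL, ENOSE_CHANNELS))
  for (c in 1:8) {
    sims[, c] <- channel_similarity(query$values[qi, c], sig$values[ri, c], eps = eps)
  }
  pass <- if (strict_inequality) sims > sim_threshold else sims >= sim_threshold
  channel_match <- apply(pass, 2L, all)
  n_matched <- sum(channel_match)
  structure(list(label = record$label,
                 similarity = colMeans(sims),
                 channel_match = channel_match,
                 n_matched = n_matched,
                 success = n_matched >= min_channels,
                 mean_similarity = mean(sims)),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("match vs '%s': %d/8 channels, %s (mean similarity %.3f)\n",
              x$label, x$n_matched, if (x$success) "success" else "failure",
              x$mean_similarity))
  invisible(x)
}

#' Match a query against the whole database
#'
#' Scores the query against every record, ranks by matched channels then
#' mean similarity (ties broken by database order), and returns the verdict:
#' the top record's label if it passes the decision rule, otherwise
#' `"unidentified"`.
#'
#' @inheritParams match_record
#' @param db An [build_database()] odor database.
#' @return List with `results` (per-record [match_record()] results, ranked),
#'   `ranking` (data.frame `label`, `n_matched`, `mean_similarity`,
#'   `success`), and `verdict`.
#' @export
match_database <- function(query, db, sim_threshold = 0.80, min_channels = 6,
                           strict_inequality = FALSE, eps = 1e-6) {
  stopifnot(inherits(db, "odor_database"))
  if (length(db$records) == 0L) stop("empty database", call. = FALSE)
  results <- lapply(db$records, match_record, query = query,
                    sim_threshold = sim_threshold, min_channels = min_channels,
                    strict_inequality = strict_inequality, eps = eps)
  nm <- vapply(results, `[[`, numeric(1), "n_matched")
  ms <- vapply(results, `[[`, numeric(1), "mean_similarity")
  ord <- order(-nm, -ms)  # stable: ties keep database order
  results <- results[ord]
  ranking <- data.frame(label = vapply(results, `[[`, character(1), "label"),
                        n_matched = vapply(results, `[[`, numeric(1), "n_matched"),
                        mean_similarity = vapply(results, `[[`, numeric(1), "mean_similarity"),
                        success = vapply(results, `[[`, logical(1), "success"),
                        stringsAsFactors = FALSE, row.names = NULL)
  verdict <- if (ranking$success[1L]) ranking$label[1L] else "unidentified"
  list(results = results, ranking = ranking, verdict = verdict)
}

#' Classification success rate
#'
#' Percentage of verdicts equal to the true labels.
#'
#' @param verdicts Character vector of predicted labels.
#' @param truths Character vector of true labels, same length.
#' @return Percentage in `[0, 100]`.
#' @export
success_rate <- function(verdicts, truths) {
  if (length(verdicts) == 0L) stop("empty verdict list", call. = FALSE)
  if (length(verdicts) != length(truths)) stop("length mismatch", call. = FALSE)
  100 * mean(verdicts == truths)
}

#' Serialize an odor database to JSON
#'
#' Stores records (label, grid, signature matrix, elite vector, provenance)
#' and, when present, the trained per-class networks.
#'
#' @param db An [build_database()] database.
#' @param path Output JSON path.
#' @return `path` invisibly; `db_from_json()` returns the database.
#' @export
db_to_json <- function(db, path) {
  stopifnot(inherits(db, "odor_database"))
  recs <- lapply(db$records, function(r) {
    list(label = r$label, t = r$signature$t, K = r$signature$K,
         signature = lapply(as.data.frame(r$signature$values), identity),
         elite = as.numeric(r$elite), provenance = r$provenance)
  })
  nets <- if (!is.null(db$nets)) {
    lapply(db$nets, function(n) list(input_size = n$input_size,
                                     hidden_size = n$hidden_size,
                                     W1 = n$W1, b1 = n$b1,
                                     W2 = as.vector(n$W2), b2 = n$b2,
                                     trained = n$trained))
  }
  jsonlite::write_json(list(K = db$K, saturations = db$saturations,
                            records = recs, nets = nets),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                       null = "null")
  invisible(path)
}

#' @rdname db_to_json
#' @export
db_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  records <- lapply(o$records, function(r) {
    vals <- do.call(cbind, lapply(r$signature[ENOSE_CHANNELS], unlist))
    sig <- structure(list(t = as.integer(unlist(r$t)), values = vals,
                          K = as.integer(r$K), role = "input", label = r$label),
                     class = "gradient_profile")
    structure(list(label = r$label, signature = sig,
                   elite = stats::setNames(as.numeric(unlist(r$elite)), ENOSE_CHANNELS),
                   provenance = unlist(r$provenance)),
              class = "reference_record")
  })
  names(records) <- vapply(records, `[[`, character(1), "label")
  nets <- NULL
  if (!is.null(o$nets)) {
    nets <- lapply(o$nets, function(n) {
      W1 <- matrix(unlist(n$W1), as.integer(n$input_size), as.integer(n$hidden_size),
                   byrow = TRUE)
      structure(list(input_size = as.integer(n$input_size),
                     hidden_size = as.integer(n$hidden_size),
                     W1 = W1, b1 = as.numeric(unlist(n$b1)),
                     W2 = matrix(unlist(n$W2), ncol = 1L),
                     b2 = as.numeric(n$b2), trained = isTRUE(n$trained)),
                class = "ann_network")
    })
  }
  structure(list(records = records, K = as.integer(o$K),
                 saturations = as.numeric(unlist(o$saturations)), nets = nets),
            class = "odor_database")
}
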