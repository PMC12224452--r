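# Searchlight decoding: the classifier applied at every (masked source,
# timepoint), features = epoch values at the searchlight's member sources,
# stratified cross-validated accuracy per cell.

#' Stratified cross-validation folds
#'
#' @param labels Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle within class.
#' @return Integer vector of fold assignments in `1..k`.
#' @keywords internal
#' @noRd
make_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("cv_folds = ", k, " exceeds the per-class epoch count (",
         paste(names(counts), counts, sep = ": ", collapse = ", "), ")",
         call. = FALSE)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# Train-fold z-scoring: parameters from the training rows only, applied to
# both; constant features pass through centered.
zscore_fold <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2L, stats::sd)
  sdv[sdv <= 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(x_train, 2L, mu, "-"), 2L, sdv, "/"),
       test = sweep(sweep(x_test, 2L, mu, "-"), 2L, sdv, "/"))
}

new_accuracy_map <- function(values, subject_id, vertices, time_ms,
                             mode = "cv") {
  structure(list(values = values, subject_id = subject_id,
                 vertices = as.integer(vertices), time_ms = time_ms,
                 chance_level = 0.5, evaluation_mode = mode),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  cat("<accuracy_map>", x$subject_id, "-", nrow(x$values), "sources x",
      ncol(x$values), "timepoints; mean",
      round(mean(x$values), 3), paste0("(", x$evaluation_mode, ")"), "\n")
  invisible(x)
}

#' Searchlight decoding of one subject's epochs
#'
#' At each (masked source, timepoint) the classifier is trained on features
#' formed by the epoch values at the searchlight's member sources at that
#' timepoint.  Features are z-scored within training folds (parameters
#' from the training fold applied to the held-out fold), which makes the
#' accuracy map invariant to per-source affine rescaling.  Accuracy is the
#' stratified cross-validated accuracy averaged over folds; with
#' `eval = "train"` the training-set accuracy of a single fit on all
#' epochs is reported instead.
#'
#' @param epochs An `epoch_set`.
#' @param neighborhoods A `neighborhoods` object built on the same mask.
#' @param spec A [classifier_spec()]; its seed also fixes the fold
#'   assignment.
#' @param cv_folds Number of stratified folds (default 5).
#' @param times_ms Optional subset of the epoch's time axis to decode
#'   (values must be on the epoch grid); defaults to all timepoints.
#' @param eval `"cv"` (default) or `"train"`.
#' @return An `accuracy_map` (masked sources x decoded timepoints).
#' @export
searchlight_decode <- function(epochs, neighborhoods,
                               spec = classifier_spec(), cv_folds = 5L,
                               times_ms = NULL, eval = c("cv", "train")) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(neighborhoods, "neighborhoods"))
  eval <- match.arg(eval)
  centers <- neighborhoods$centers
  member_pos <- lapply(neighborhoods$members, match, table = epochs$vertices)
  if (anyNA(unlist(member_pos, use.names = FALSE)))
    stop("neighborhoods reference vertices absent from the epoch set; ",
         "they must be built on the same mask", call. = FALSE)

  if (is.null(times_ms)) {
    tidx <- seq_along(epochs$time_ms)
  } else {
    tidx <- match(times_ms, epochs$time_ms)
    if (anyNA(tidx))
      stop("`times_ms` contains values off the epoch time grid",
           call. = FALSE)
  }

  labels <- epochs$labels
  n_ep <- length(labels)
  pos_lv <- levels(labels)[2L]
  y01 <- as.numeric(labels == pos_lv)
  k_feat <- length(member_pos[[1L]])
  Wts <- init_weights(k_feat, spec)

  if (eval == "cv") {
    folds <- make_folds(labels, cv_folds, spec$seed)
    fold_idx <- lapply(seq_len(cv_folds), function(f) which(folds == f))
  }

  values <- matrix(NA_real_, length(centers), length(tidx))
  for (ci in seq_along(centers)) {
    pos <- member_pos[[ci]]
    for (ti in seq_along(tidx)) {
      x <- epochs$data[, pos, tidx[ti], drop = FALSE][, , 1L, drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
      if (eval == "train") {
        z <- zscore_fold(x, x)
        net <- ffnn_fit_raw(z$train, y01, spec, Wts)
        pred <- as.vector(stats::predict(net, z$train)) > 0.5
        values[ci, ti] <- mean(pred == (y01 == 1))
      } else {
        acc <- vapply(fold_idx, function(te) {
          z <- zscore_fold(x[-te, , drop = FALSE], x[te, , drop = FALSE])
          net <- ffnn_fit_raw(z$train, y01[-te], spec, Wts)
          pred <- as.vector(stats::predict(net, z$test)) > 0.5
          mean(pred == (y01[te] == 1))
        }, numeric(1))
        values[ci, ti] <- mean(acc)
      }
    }
  }
  new_accuracy_map(values, epochs$subject_id, centers,
                   epochs$time_ms[tidx], mode = eval)
}

#' Searchlight decoding of residualized epochs
#'
#' Identical to [searchlight_decode()]; kept as a separate entry point so
#' pipeline reports can tag accuracy maps computed on confound-regression
#' residuals.
#'
#' @inheritParams searchlight_decode
#' @return An `accuracy_map` with `evaluation_mode` suffixed
#'   `"_residual"`.
#' @export
decode_residuals <- function(epochs, neighborhoods,
                             spec = classifier_spec(), cv_folds = 5L,
                             times_ms = NULL) {
  map <- searchlight_decode(epochs, neighborhoods, spec, cv_folds, times_ms)
  map$evaluation_mode <- paste0(map$evaluation_mode, "_residual")
  map
}

#' Shuffle epoch labels (chance-level control)
#'
#' @param epochs An `epoch_set`.
#' @param seed Integer seed.
#' @return The epoch set with labels permuted.
#' @export
shuffle_labels <- function(epochs, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$labels <- with_seed(seed, sample(epochs$labels))
  epochs
}
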