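# Temporal generalization across paradigms: classifiers trained at each
# training-paradigm timepoint on a fixed source set, tested at every
# timepoint of the other paradigm.

#' Temporal generalization matrix
#'
#' For each training timepoint inside `train_window_ms`, the classifier is
#' fit on the training paradigm's epoch values at `source_set` (all
#' training epochs; no cross-validation, since evaluation is on the other
#' paradigm) and tested at every timepoint of the test set.  Z-scoring
#' parameters are learned from the training data only.
#'
#' @param train,test `epoch_set`s of the two paradigms.
#' @param source_set Mesh vertex indices used as features (ascending
#'   order is enforced).
#' @param train_window_ms Length-2 window of training timepoints, in ms.
#' @param spec A [classifier_spec()].
#' @return A `tgm_matrix`: `values` (train times x test times, in
#'   `[0, 1]`), `train_time_ms`, `test_time_ms`, `source_set`,
#'   `train_paradigm`, `test_paradigm`, `subject_id`.
#' @export
tgm <- function(train, test, source_set, train_window_ms,
                spec = classifier_spec()) {
  stopifnot(inherits(train, "epoch_set"), inherits(test, "epoch_set"))
  source_set <- sort(unique(as.integer(source_set)))
  pos_tr <- match(source_set, train$vertices)
  pos_te <- match(source_set, test$vertices)
  if (anyNA(pos_tr) || anyNA(pos_te))
    stop("`source_set` contains vertices absent from the train or test ",
         "epoch sets", call. = FALSE)
  stopifnot(length(train_window_ms) == 2L)
  tr_idx <- which(train$time_ms >= train_window_ms[1] &
                  train$time_ms <= train_window_ms[2])
  if (length(tr_idx) == 0L)
    stop("`train_window_ms` contains no training timepoints", call. = FALSE)

  y_tr <- as.numeric(train$labels == levels(train$labels)[2L])
  y_te <- as.numeric(test$labels == levels(test$labels)[2L])
  if (length(unique(y_tr)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  Wts <- init_weights(length(source_set), spec)

  n_te_t <- length(test$time_ms)
  values <- matrix(NA_real_, length(tr_idx), n_te_t)
  for (i in seq_along(tr_idx)) {
    x_tr <- train$data[, pos_tr, tr_idx[i], drop = FALSE][, , 1L]
    mu <- colMeans(x_tr)
    sdv <- apply(x_tr, 2L, stats::sd)
    sdv[sdv <= 0 | !is.finite(sdv)] <- 1
    z_tr <- sweep(sweep(x_tr, 2L, mu, "-"), 2L, sdv, "/")
    net <- ffnn_fit_raw(z_tr, y_tr, spec, Wts)
    for (j in seq_len(n_te_t)) {
      x_te <- test$data[, pos_te, j, drop = FALSE][, , 1L]
      z_te <- sweep(sweep(x_te, 2L, mu, "-"), 2L, sdv, "/")
      pred <- as.vector(stats::predict(net, z_te)) > 0.5
      values[i, j] <- mean(pred == (y_te == 1))
    }
  }
  structure(list(values = values,
                 train_time_ms = train$time_ms[tr_idx],
                 test_time_ms = test$time_ms,
                 source_set = source_set,
                 train_paradigm = train$paradigm,
                 test_paradigm = test$paradigm,
                 subject_id = train$subject_id),
            class = "tgm_matrix")
}

#' @export
print.tgm_matrix <- function(x, ...) {
  cat("<tgm_matrix>", x$subject_id, ":", x$train_paradigm, "->",
      x$test_paradigm, "-", nrow(x$values), "x", ncol(x$values),
      "cells; mean", round(mean(x$values), 3), "\n")
  invisible(x)
}

#' Restrict TGM training to a significant cluster
#'
#' Extracts the vertex set and training window from a spatiotemporal
#' cluster, mirroring the approach of training only the classifiers that
#' fell inside the significant cluster of the within-paradigm searchlight
#' analysis.
#'
#' @param cluster A `cluster_result` from [sign_flip_permutation()].
#' @return List with `source_set` (vertex ids) and `train_window_ms`
#'   (`[min, max]` of cluster timepoints).
#' @export
restrict_to_cluster <- function(cluster) {
  if (is.null(cluster) || length(cluster$nodes %||% integer(0)) == 0L)
    stop("no significant cluster: temporal generalization requires a ",
         "non-empty spatiotemporal cluster", call. = FALSE)
  stopifnot(inherits(cluster, "cluster_result"))
  if (is.null(cluster$vertices))
    stop("cluster is not spatiotemporal (no vertex members)", call. = FALSE)
  list(source_set = cluster$vertices,
       train_window_ms = range(cluster$times_ms))
}
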