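# Embedding-side analyses: word-position residualization, per-layer cosine
# distances between condition means, and cross-context classification of
# phrase vs. noun embeddings from a pluggable provider.

#' Residualize embeddings against word position
#'
#' Per layer and embedding dimension, OLS of the values on the binary
#' word-position indicator plus intercept across items; the output is the
#' residuals.  This removes the confound that single nouns are the first
#' token while phrase nouns are not: afterwards the per-position group
#' means are equal in every dimension.  Idempotent.
#'
#' @param set An `embedding_set` with both position values present.
#' @return The residualized `embedding_set`.
#' @export
position_residualize <- function(set) {
  stopifnot(inherits(set, "embedding_set"))
  pos <- set$meta$word_position
  if (length(unique(pos)) < 2L)
    stop("both word-position values must be present", call. = FALSE)
  ind <- as.numeric(pos == sort(unique(pos))[2L])
  qx <- qr(cbind(1, ind))
  for (l in seq_len(dim(set$values)[1L]))
    set$values[l, , ] <- qr.resid(qx, set$values[l, , ])
  set
}

#' Per-layer cosine distance between condition means
#'
#' `1 - cos(mean phrase vector, mean noun vector)` per layer, within one
#' context.
#'
#' @param set An `embedding_set`.
#' @param context `"two_word"` or `"naturalistic"`.
#' @return Numeric vector, one distance per layer.
#' @export
layer_cosine_distance <- function(set, context = c("two_word",
                                                   "naturalistic")) {
  stopifnot(inherits(set, "embedding_set"))
  context <- match.arg(context)
  in_ctx <- set$meta$context == context
  for (cls in c("noun", "phrase"))
    if (!any(in_ctx & set$meta$class == cls))
      stop("class '", cls, "' absent in context '", context, "'",
           call. = FALSE)
  n_layers <- dim(set$values)[1L]
  vapply(seq_len(n_layers), function(l) {
    m <- set$values[l, , , drop = FALSE][1L, , ]
    mu_p <- colMeans(m[in_ctx & set$meta$class == "phrase", , drop = FALSE])
    mu_n <- colMeans(m[in_ctx & set$meta$class == "noun", , drop = FALSE])
    np <- sqrt(sum(mu_p^2)); nn <- sqrt(sum(mu_n^2))
    if (np == 0 || nn == 0)
      stop("zero-norm condition mean vector in layer ", l, call. = FALSE)
    1 - sum(mu_p * mu_n) / (np * nn)
  }, numeric(1))
}

#' Cross-context classification of embeddings
#'
#' Fits the feed-forward classifier on the chosen layer's items of the
#' training context and reports both the fit-set accuracy and the accuracy
#' on the other context's items.  Apply [position_residualize()] first to
#' remove the word-position confound.
#'
#' @param set An `embedding_set`.
#' @param train_context `"two_word"` or `"naturalistic"`.
#' @param layer Layer index (default: the last layer).
#' @param spec A [classifier_spec()].
#' @return List with `train_accuracy` and `test_accuracy`.
#' @export
cross_context_classify <- function(set,
                                   train_context = c("two_word",
                                                     "naturalistic"),
                                   layer = NULL,
                                   spec = classifier_spec()) {
  stopifnot(inherits(set, "embedding_set"))
  train_context <- match.arg(train_context)
  n_layers <- dim(set$values)[1L]
  layer <- layer %||% n_layers
  if (!is_count(layer) || layer > n_layers)
    stop("`layer` index out of range (1..", n_layers, ")", call. = FALSE)
  test_context <- setdiff(c("two_word", "naturalistic"), train_context)
  tr <- set$meta$context == train_context
  te <- set$meta$context == test_context
  if (!any(tr) || !any(te))
    stop("both contexts must be populated", call. = FALSE)
  m <- set$values[layer, , , drop = FALSE][1L, , ]
  z <- zscore_fold(m[tr, , drop = FALSE], m[te, , drop = FALSE])
  fit <- fit_classifier(z$train, set$meta$class[tr], spec)
  pred_tr <- predict(fit, z$train)
  pred_te <- predict(fit, z$test)
  list(train_accuracy = mean(pred_tr == set$meta$class[tr]),
       test_accuracy = mean(pred_te == set$meta$class[te]))
}
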