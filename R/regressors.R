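# The seven word-level confound regressors for naturalistic stimuli:
# prosodic peaks, word rate, log frequency, surprisal, and sentence-level
# emotional valence/arousal, plus z-scoring, collinearity reporting, ISC,
# and mass-univariate residualization of epochs.

#' Peak prosody per word
#'
#' Maximum RMS intensity and f0 among frames whose start time lies in the
#' half-open word interval `[onset, onset + duration)`.
#'
#' @param frames data.frame with `time_ms`, `rms`, `f0` (10 ms frames).
#' @param word_table Word annotation table with `word_id`, `onset_ms`,
#'   `duration_ms`.
#' @return data.frame with `word_id`, `peak_rms`, `peak_f0`.
#' @export
peak_prosody <- function(frames, word_table) {
  stopifnot(all(c("time_ms", "rms", "f0") %in% names(frames)))
  out <- data.frame(word_id = word_table$word_id,
                    peak_rms = NA_real_, peak_f0 = NA_real_,
                    stringsAsFactors = FALSE)
  for (w in seq_len(nrow(word_table))) {
    on <- word_table$onset_ms[w]
    sel <- frames$time_ms >= on &
      frames$time_ms < on + word_table$duration_ms[w]
    if (!any(sel))
      stop("no prosody frame covers word '", word_table$word_id[w], "'",
           call. = FALSE)
    out$peak_rms[w] <- max(frames$rms[sel])
    out$peak_f0[w] <- max(frames$f0[sel])
  }
  out
}

#' Word presentation rate
#'
#' Duration of the word in milliseconds divided by its letter count; slow
#' rates are long words of few letters.
#'
#' @param duration_ms Word duration(s) in ms (> 0).
#' @param n_letters Letter count(s) (>= 1).
#' @return Numeric, ms per letter.
#' @export
word_rate <- function(duration_ms, n_letters) {
  if (any(duration_ms <= 0)) stop("`duration_ms` must be positive",
                                  call. = FALSE)
  if (any(n_letters < 1)) stop("`n_letters` must be >= 1", call. = FALSE)
  duration_ms / n_letters
}

#' Log-transformed unigram frequency
#'
#' @param count Unigram count(s) (>= 1; no zero-count smoothing).
#' @param base Logarithm base (default natural log).
#' @return Numeric log-counts.
#' @export
log_frequency <- function(count, base = exp(1)) {
  if (any(count < 1)) stop("`count` must be >= 1", call. = FALSE)
  log(count, base = base)
}

#' Surprisal of a probability
#'
#' The negative logarithm of the probability assigned to the actual next
#' word; base 2 (bits) by default.
#'
#' @param probability Probability value(s) in `(0, 1]`.
#' @param base Logarithm base (default 2).
#' @return Numeric surprisal values.
#' @export
surprisal <- function(probability, base = 2) {
  if (any(probability <= 0 | probability > 1))
    stop("`probability` must lie in (0, 1]", call. = FALSE)
  -log(probability, base = base)
}

#' Language-model surprisal per word
#'
#' Applies [surprisal()] to `P(word | preceding words of the same
#' sentence)` obtained from a pluggable provider; context resets at
#' sentence boundaries (the first word of a sentence sees an empty
#' context).
#'
#' @param word_table Word table with `token` and `sentence_index`.
#' @param provider Function `f(token, context_tokens)` returning a
#'   probability in `(0, 1]`.
#' @param base Logarithm base (default 2, bits).
#' @return Numeric surprisal per word, in table order.
#' @export
lm_surprisal <- function(word_table, provider, base = 2) {
  stopifnot(is.function(provider))
  n <- nrow(word_table)
  out <- numeric(n)
  for (i in seq_len(n)) {
    same <- word_table$sentence_index == word_table$sentence_index[i]
    context <- word_table$token[same & seq_len(n) < i]
    p <- provider(word_table$token[i], context)
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) ||
        p <= 0 || p > 1)
      stop("provider returned an invalid probability for word index ", i,
           call. = FALSE)
    out[i] <- surprisal(p, base = base)
  }
  out
}

#' Uniform-vocabulary probability provider
#'
#' Assigns every word probability `1 / vocab_size`; with the default
#' base-2 surprisal, a vocabulary of 1024 gives 10 bits everywhere.
#'
#' @param vocab_size Vocabulary size (>= 1).
#' @return A provider function for [lm_surprisal()].
#' @export
uniform_provider <- function(vocab_size) {
  stopifnot(is_count(vocab_size))
  force(vocab_size)
  function(token, context) 1 / vocab_size
}

#' Broadcast sentence-level emotion ratings to words
#'
#' Per-sentence across-rater means, assigned identically to every word of
#' the sentence.
#'
#' @param valence_ratings,arousal_ratings Rater x sentence matrices
#'   (columns indexed by sentence).
#' @param word_table Word table with `sentence_index`.
#' @return data.frame with `word_id`, `valence`, `arousal`.
#' @export
propagate_sentence_emotion <- function(valence_ratings, arousal_ratings,
                                       word_table) {
  si <- word_table$sentence_index
  if (any(si < 1L) || any(si > ncol(valence_ratings)) ||
      any(si > ncol(arousal_ratings)))
    stop("sentence index missing from the ratings matrices", call. = FALSE)
  data.frame(word_id = word_table$word_id,
             valence = colMeans(valence_ratings)[si],
             arousal = colMeans(arousal_ratings)[si],
             stringsAsFactors = FALSE)
}

#' Inter-subject correlation of ratings
#'
#' Per rater, the Pearson correlation of that rater's ratings with the
#' across-rater mean ratings; ISC is the mean over raters.
#'
#' @param ratings Rater x sentence matrix; >= 2 raters, >= 3 sentences.
#' @param strict If `TRUE`, a zero-variance rater is an error; otherwise
#'   it is excluded with a warning.
#' @return List with `per_rater` (named correlations) and `mean_isc`.
#' @export
isc <- function(ratings, strict = FALSE) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L) stop("need >= 2 raters", call. = FALSE)
  if (ncol(ratings) < 3L) stop("need >= 3 sentences", call. = FALSE)
  v <- apply(ratings, 1L, stats::sd)
  if (any(v <= 0)) {
    if (strict)
      stop("zero-variance rater(s): ",
           paste(rownames(ratings)[v <= 0] %||% which(v <= 0),
                 collapse = ", "), call. = FALSE)
    warning(sum(v <= 0), " zero-variance rater(s) excluded from ISC")
    ratings <- ratings[v > 0, , drop = FALSE]
    if (nrow(ratings) < 2L) stop("fewer than 2 raters remain", call. = FALSE)
  }
  grand <- colMeans(ratings)
  r <- apply(ratings, 1L, stats::cor, y = grand)
  list(per_rater = r, mean_isc = mean(r))
}

#' Z-score regressor columns
#'
#' Column-wise `(x - mean) / sd` with the n-1 SD; idempotent up to
#' floating point.  A zero-SD column is an error naming the column.
#'
#' @param table Regressor table (data.frame); only the seven regressor
#'   columns are transformed, id columns pass through.
#' @return The table with z-scored regressors and attribute
#'   `zscored = TRUE`.
#' @export
zscore_columns <- function(table) {
  cols <- intersect(REGRESSOR_NAMES, names(table))
  if (length(cols) == 0L) stop("no regressor columns found", call. = FALSE)
  m <- as.matrix(table[cols])
  if (any(!is.finite(m))) stop("non-finite regressor values", call. = FALSE)
  table[cols] <- zscore_matrix(m, on_zero_sd = "error", names = cols)
  attr(table, "zscored") <- TRUE
  table
}

#' Pairwise collinearity report
#'
#' @param table Regressor table (z-scored or raw).
#' @param threshold Absolute correlation above which a pair is flagged
#'   (default 0.7).
#' @return List with `correlation` (symmetric matrix, unit diagonal),
#'   `max_abs_r` (largest off-diagonal magnitude), and `flagged`
#'   (data.frame of offending pairs).
#' @export
collinearity_report <- function(table, threshold = 0.7) {
  cols <- intersect(REGRESSOR_NAMES, names(table))
  cm <- stats::cor(as.matrix(table[cols]))
  diag(cm) <- 1
  off <- abs(cm); diag(off) <- 0
  idx <- which(off > threshold & upper.tri(off), arr.ind = TRUE)
  flagged <- data.frame(var1 = cols[idx[, 1L]], var2 = cols[idx[, 2L]],
                        r = cm[idx], stringsAsFactors = FALSE)
  list(correlation = cm, max_abs_r = max(off), flagged = flagged)
}

#' Residualize epochs against the confound regressors
#'
#' Per (source, timepoint), the z-scored epoch values across epochs are
#' regressed by OLS on the seven z-scored regressors plus an intercept;
#' the output epochs are the residuals, orthogonal to every regressor
#' column.  Residualization is idempotent.
#'
#' @param epochs A naturalistic `epoch_set` carrying `word_ids`.
#' @param table A z-scored regressor table aligned to the epochs by
#'   `word_id` (same order).
#' @return An `epoch_set` of residuals (`residualized = TRUE`).
#' @export
residualize_epochs <- function(epochs, table) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!isTRUE(attr(table, "zscored")))
    stop("regressor table must be z-scored first (see zscore_columns)",
         call. = FALSE)
  if (is.null(epochs$word_ids) ||
      !identical(as.character(epochs$word_ids),
                 as.character(table$word_id)))
    stop("epoch word_ids and regressor table rows are misaligned",
         call. = FALSE)
  cols <- intersect(REGRESSOR_NAMES, names(table))
  X <- cbind(`(Intercept)` = 1, as.matrix(table[cols]))
  n_ep <- dim(epochs$data)[1]
  if (n_ep <= ncol(X))
    stop("need more epochs (", n_ep, ") than regressors plus intercept (",
         ncol(X), ")", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient regressor design; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  d <- dim(epochs$data)
  Y <- matrix(epochs$data, nrow = d[1])          # epochs x (sources*times)
  # The dependent variable is z-scored per (source, time) across epochs on
  # the first pass only; residuals are not re-standardized, which keeps
  # residualization idempotent.
  if (!isTRUE(epochs$residualized))
    Y <- zscore_matrix(Y, on_zero_sd = "center")
  R <- qr.resid(qx, Y)
  epochs$data <- array(R, dim = d)
  epochs$residualized <- TRUE
  epochs
}
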