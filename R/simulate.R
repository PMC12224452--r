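# Synthetic source-space data: epochs with controllable class effects and
# confound loadings, word annotation tables, prosody frames, rating
# matrices, and synthetic embedding sets.  Every generator is a pure
# function of (config, seed).

REGRESSOR_NAMES <- c("peak_rms", "peak_f0", "word_rate", "log_frequency",
                     "surprisal", "valence", "arousal")

#' Specify an injected class effect
#'
#' A fixed unit-norm spatial pattern over `vertices` (drawn once from
#' `pattern_seed`) times `amplitude` is added to phrase-class epochs inside
#' `time_window_ms`.  This is the synthetic stand-in for the
#' phrase-vs-noun composition contrast.
#'
#' @param vertices Mesh vertex indices carrying the effect.
#' @param time_window_ms Length-2 numeric, closed window in ms within
#'   `[0, 875]`.
#' @param amplitude Signal units (>= 0) added along the unit-norm pattern.
#' @param pattern_seed Integer fixing the spatial pattern.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(vertices, time_window_ms, amplitude,
                        pattern_seed = 1L) {
  stopifnot(length(time_window_ms) == 2L)
  if (!(time_window_ms[1] < time_window_ms[2]))
    stop("effect window start must precede end", call. = FALSE)
  if (time_window_ms[1] < 0 || time_window_ms[2] > 875)
    stop("effect window must lie within [0, 875] ms", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  structure(list(vertices = as.integer(vertices),
                 time_window_ms = as.numeric(time_window_ms),
                 amplitude = as.numeric(amplitude),
                 pattern_seed = as.integer(pattern_seed)),
            class = "effect_spec")
}

#' Specify a class-correlated confound loading (naturalistic paradigm)
#'
#' The named regressor is drawn standard-normal per epoch, shifted by
#' `class_shift` SD for phrase-class epochs, and its z-scored value times
#' `loading_gain` times a fixed unit-norm pattern is added to the epoch at
#' `loading_vertices` inside `loading_window_ms`.  This emulates stimulus
#' properties of naturalistic narratives that correlate with the phrase
#' class and add a class-separable late signal of their own.
#'
#' @param regressor_name One of `peak_rms, peak_f0, word_rate,
#'   log_frequency, surprisal, valence, arousal`.
#' @param class_shift Standardized mean difference between classes.
#' @param loading_vertices Mesh vertex indices carrying the loading.
#' @param loading_window_ms Closed window in ms within `[0, 875]`.
#' @param loading_gain Signal units per regressor SD.
#' @param pattern_seed Integer fixing the loading pattern.
#' @return A `confound_spec`.
#' @export
confound_spec <- function(regressor_name, class_shift = 0,
                          loading_vertices = integer(0),
                          loading_window_ms = c(0, 875),
                          loading_gain = 0, pattern_seed = 2L) {
  if (!regressor_name %in% REGRESSOR_NAMES)
    stop("unknown regressor name '", regressor_name, "'; must be one of: ",
         paste(REGRESSOR_NAMES, collapse = ", "), call. = FALSE)
  stopifnot(length(loading_window_ms) == 2L)
  if (loading_window_ms[1] < 0 || loading_window_ms[2] > 875)
    stop("loading window must lie within [0, 875] ms", call. = FALSE)
  structure(list(regressor_name = regressor_name,
                 class_shift = as.numeric(class_shift),
                 loading_vertices = as.integer(loading_vertices),
                 loading_window_ms = as.numeric(loading_window_ms),
                 loading_gain = as.numeric(loading_gain),
                 pattern_seed = as.integer(pattern_seed)),
            class = "confound_spec")
}

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic source-space generator:
#' geometry, epoch grid (200 Hz, half-open `[0, 875)` ms by default, i.e.
#' 175 samples at 5 ms steps), the noise model (independent Gaussian noise
#' smoothed on the mesh and AR(1)-filtered in time), injected class
#' effects per paradigm, and class-correlated confound loadings for the
#' naturalistic paradigm.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_epochs_per_class Epochs per class per subject (class balance is
#'   enforced so 50% is a valid chance level).
#' @param mesh_level Icosphere subdivision level.
#' @param mask_regions Region names forming the language mask (default: all
#'   six caps of [default_region_spec()]).
#' @param epoch_ms Length-2 half-open epoch span in ms; must align to the
#'   5 ms grid of the 200 Hz sample rate.
#' @param noise_sd SD of the independent Gaussian noise before filtering.
#' @param spatial_smoothing_passes Number of neighbor-averaging passes.
#' @param temporal_ar1_phi AR(1) coefficient in `[0, 1)`.
#' @param effects Named list (`two_word`, `naturalistic`) of lists of
#'   [effect_spec()]s.
#' @param confounds List of [confound_spec()]s (naturalistic only).
#' @param master_seed Master seed; all draws derive from it.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_subjects = 10L,
                       n_epochs_per_class = 40L,
                       mesh_level = 2L,
                       mask_regions = c("LATL", "LMTG", "LIFG",
                                        "LvmPFC", "LAG", "LSMG"),
                       epoch_ms = c(0, 875),
                       noise_sd = 1,
                       spatial_smoothing_passes = 2L,
                       temporal_ar1_phi = 0.3,
                       effects = list(two_word = list(),
                                      naturalistic = list()),
                       confounds = list(),
                       master_seed = 42L) {
  if (!is_count(n_subjects, 2L)) stop("`n_subjects` must be >= 2",
                                      call. = FALSE)
  if (!is_count(n_epochs_per_class, 2L))
    stop("`n_epochs_per_class` must be >= 2", call. = FALSE)
  if (temporal_ar1_phi < 0 || temporal_ar1_phi >= 1)
    stop("`temporal_ar1_phi` must lie in [0, 1)", call. = FALSE)
  stopifnot(length(epoch_ms) == 2L, epoch_ms[1] < epoch_ms[2])
  if (epoch_ms[1] < 0 || epoch_ms[2] > 875)
    stop("`epoch_ms` must lie within [0, 875]", call. = FALSE)
  step <- 1000 / 200
  if (any(abs(epoch_ms / step - round(epoch_ms / step)) > 1e-9))
    stop("`epoch_ms` must align to the 5 ms grid", call. = FALSE)
  stopifnot(is.list(effects))
  for (p in names(effects))
    stopifnot(all(vapply(effects[[p]], inherits, logical(1), "effect_spec")))
  stopifnot(all(vapply(confounds, inherits, logical(1), "confound_spec")))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_epochs_per_class = as.integer(n_epochs_per_class),
                 mesh_level = as.integer(mesh_level),
                 mask_regions = mask_regions,
                 sample_rate_hz = 200,
                 epoch_ms = as.numeric(epoch_ms),
                 noise_sd = as.numeric(noise_sd),
                 spatial_smoothing_passes = as.integer(spatial_smoothing_passes),
                 temporal_ar1_phi = as.numeric(temporal_ar1_phi),
                 effects = effects,
                 confounds = confounds,
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

# Geometry implied by a sim_config (mesh with default regions + mask).
config_geometry <- function(config) {
  mesh <- build_icosphere(config$mesh_level)
  mesh <- assign_regions(mesh, default_region_spec(mesh))
  mask <- make_language_mask(mesh, config$mask_regions)
  list(mesh = mesh, mask = mask)
}

config_times_ms <- function(config) {
  step <- 1000 / config$sample_rate_hz
  seq(config$epoch_ms[1], config$epoch_ms[2] - step, by = step)
}

# Unit-norm pattern over a vertex set, fixed by seed.
unit_pattern <- function(n, seed) {
  z <- with_seed(seed, stats::rnorm(n))
  z / sqrt(sum(z^2))
}

# Noise core: iid Gaussian -> spatial neighbor-averaging -> AR(1) in time.
# Returns epochs x mask x times array.
simulate_noise <- function(n_epochs, geom, times, config) {
  n_mask <- length(geom$mask$vertices)
  n_times <- length(times)
  x <- array(stats::rnorm(n_epochs * n_mask * n_times, sd = config$noise_sd),
             dim = c(n_epochs, n_mask, n_times))
  if (config$spatial_smoothing_passes > 0L) {
    me <- mask_edge_positions(geom$mesh, geom$mask)
    A <- diag(n_mask)
    if (nrow(me) > 0L) {
      A[me] <- 1
      A[me[, c(2L, 1L)]] <- 1
    }
    A <- A / rowSums(A)
    flat <- matrix(aperm(x, c(2L, 1L, 3L)), nrow = n_mask)
    for (i in seq_len(config$spatial_smoothing_passes)) flat <- A %*% flat
    x <- aperm(array(flat, dim = c(n_mask, n_epochs, n_times)),
               c(2L, 1L, 3L))
  }
  phi <- config$temporal_ar1_phi
  if (phi > 0 && n_times > 1L) {
    for (t in 2:n_times) x[, , t] <- x[, , t] + phi * x[, , t - 1L]
  }
  x
}

add_effect <- function(data, eff, labels, geom, times) {
  pos <- match(eff$vertices, geom$mask$vertices)
  if (anyNA(pos))
    stop("effect vertices outside the language mask: ",
         paste(eff$vertices[is.na(pos)], collapse = ", "), call. = FALSE)
  tidx <- which(times >= eff$time_window_ms[1] &
                times <= eff$time_window_ms[2])
  if (length(tidx) == 0L) return(data)
  pattern <- unit_pattern(length(pos), eff$pattern_seed)
  bump <- eff$amplitude * pattern
  phr <- which(labels == "phrase")
  for (t in tidx)
    data[phr, pos, t] <- sweep(data[phr, pos, t, drop = FALSE][, , 1L],
                               2L, bump, "+")
  data
}

new_epoch_set <- function(data, labels, times, subject_id, paradigm,
                          vertices, word_ids = NULL, residualized = FALSE) {
  structure(list(data = data,
                 labels = factor(labels, levels = c("noun", "phrase")),
                 time_ms = times,
                 subject_id = subject_id,
                 paradigm = paradigm,
                 vertices = as.integer(vertices),
                 word_ids = word_ids,
                 residualized = residualized),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set>", x$subject_id, x$paradigm,
      if (isTRUE(x$residualized)) "(residualized)" else "", "-",
      d[1], "epochs x", d[2], "sources x", d[3], "timepoints\n")
  invisible(x)
}

#' Simulate labeled source-space epochs for one subject
#'
#' Noise is independent Gaussian per (epoch, source, time), spatially
#' smoothed by neighbor averaging on the mesh, then AR(1)-filtered along
#' time; injected effects are then added to phrase-class epochs.  The
#' per-subject seed derives deterministically from the config's master
#' seed, the subject id and the paradigm, so the same call is bit-identical
#' across runs.
#'
#' @param config A [sim_config()].
#' @param paradigm `"two_word"` or `"naturalistic"`.
#' @param subject_id Subject identifier string.
#' @param geometry Optional precomputed `list(mesh, mask)` to avoid
#'   rebuilding the mesh per subject.
#' @return An `epoch_set`: `data` (epochs x masked sources x timepoints),
#'   `labels` (`noun`/`phrase`, balanced), `time_ms`, `vertices` (mask
#'   vertex ids), `subject_id`, `paradigm`.
#' @export
simulate_epochs <- function(config, paradigm = c("two_word", "naturalistic"),
                            subject_id = "s01", geometry = NULL) {
  stopifnot(inherits(config, "sim_config"))
  paradigm <- match.arg(paradigm)
  geom <- geometry %||% config_geometry(config)
  times <- config_times_ms(config)
  n_ep <- 2L * config$n_epochs_per_class
  labels <- rep(c("noun", "phrase"), each = config$n_epochs_per_class)
  seed <- derive_seed(config$master_seed, subject_id, paradigm)
  data <- with_seed(seed, simulate_noise(n_ep, geom, times, config))
  for (eff in config$effects[[paradigm]] %||% list())
    data <- add_effect(data, eff, labels, geom, times)
  new_epoch_set(data, labels, times, subject_id, paradigm,
                geom$mask$vertices)
}

#' Simulate a naturalistic epoch set with confound regressors
#'
#' Draws the seven word-level regressors per epoch (standard normal, with
#' each confound's `class_shift` added for phrase-class epochs), adds each
#' confound's loading (`loading_gain` x z-scored regressor x fixed unit
#' pattern at its vertices/window), and applies the config's genuine
#' naturalistic effects as in [simulate_epochs()].  The returned table
#' records the drawn values pre-z-scoring, keyed by `word_id` in epoch
#' order.
#'
#' @inheritParams simulate_epochs
#' @return A list with `epochs` (an `epoch_set` carrying `word_ids`) and
#'   `table` (data.frame: `word_id`, `sentence_index`, the seven
#'   regressors).
#' @export
simulate_naturalistic_with_confounds <- function(config, subject_id = "s01",
                                                 geometry = NULL) {
  stopifnot(inherits(config, "sim_config"))
  geom <- geometry %||% config_geometry(config)
  es <- simulate_epochs(config, "naturalistic", subject_id, geom)
  n_ep <- dim(es$data)[1]
  labels <- es$labels
  seed <- derive_seed(config$master_seed, subject_id, "regressors")
  reg <- with_seed(seed, {
    m <- matrix(stats::rnorm(n_ep * length(REGRESSOR_NAMES)), nrow = n_ep,
                dimnames = list(NULL, REGRESSOR_NAMES))
    m
  })
  for (cf in config$confounds) {
    reg[labels == "phrase", cf$regressor_name] <-
      reg[labels == "phrase", cf$regressor_name] + cf$class_shift
  }
  for (cf in config$confounds) {
    if (cf$loading_gain == 0 || length(cf$loading_vertices) == 0L) next
    pos <- match(cf$loading_vertices, geom$mask$vertices)
    if (anyNA(pos))
      stop("confound loading vertices outside the language mask",
           call. = FALSE)
    tidx <- which(es$time_ms >= cf$loading_window_ms[1] &
                  es$time_ms <= cf$loading_window_ms[2])
    v <- reg[, cf$regressor_name]
    z <- (v - mean(v)) / stats::sd(v)
    pattern <- unit_pattern(length(pos), cf$pattern_seed)
    add <- (cf$loading_gain * z) %o% pattern   # epochs x vertices
    for (t in tidx) es$data[, pos, t] <- es$data[, pos, t] + add
  }
  word_ids <- sprintf("w%04d", seq_len(n_ep))
  es$word_ids <- word_ids
  tab <- data.frame(word_id = word_ids,
                    sentence_index = ((seq_len(n_ep) - 1L) %/% 5L) + 1L,
                    reg, stringsAsFactors = FALSE)
  list(epochs = es, table = tab)
}

#' Simulate a word annotation table
#'
#' Non-overlapping consecutive word intervals with durations uniform on
#' `[150, 600]` ms and letter counts uniform on `{2, ..., 10}`; words are
#' split over sentences in contiguous runs of roughly equal length.
#'
#' @param n_words Number of words (>= `n_sentences`).
#' @param n_sentences Number of sentences (>= 1).
#' @param seed Integer seed.
#' @return data.frame with `word_id`, `token`, `onset_ms`, `duration_ms`,
#'   `n_letters`, `sentence_index`, `unigram_count`.
#' @export
simulate_word_table <- function(n_words, n_sentences = 1L, seed = 1L) {
  if (!is_count(n_words) || !is_count(n_sentences) || n_words < n_sentences)
    stop("need `n_words` >= `n_sentences` >= 1", call. = FALSE)
  with_seed(seed, {
    duration <- stats::runif(n_words, 150, 600)
    onset <- c(0, cumsum(duration)[-n_words])
    n_letters <- sample(2:10, n_words, replace = TRUE)
    token <- vapply(n_letters, function(k)
      paste(sample(letters, k, replace = TRUE), collapse = ""), character(1))
    sentence_index <- sort(rep_len(seq_len(n_sentences), n_words))
    unigram_count <- pmax(1, round(stats::rlnorm(n_words, meanlog = 8,
                                                 sdlog = 2)))
    data.frame(word_id = sprintf("w%04d", seq_len(n_words)),
               token = token,
               onset_ms = onset,
               duration_ms = duration,
               n_letters = as.integer(n_letters),
               sentence_index = as.integer(sentence_index),
               unigram_count = unigram_count,
               stringsAsFactors = FALSE)
  })
}

#' Simulate 10 ms prosody frames for a word table
#'
#' One frame per `frame_ms` covering the full audio span.  Within each word
#' the series is a smooth sinusoidal bump; the realized per-word maxima are
#' returned separately as ground truth for recovery tests (they are the
#' generator's own record, not part of the observable frame series).
#'
#' @param word_table A table from [simulate_word_table()].
#' @param frame_ms Frame step in ms (default 10).
#' @param seed Integer seed.
#' @return list with `frames` (data.frame `time_ms`, `rms`, `f0`) and
#'   `ground_truth` (data.frame `word_id`, `sim_true_peak_rms`,
#'   `sim_true_peak_f0`).
#' @export
simulate_prosody_frames <- function(word_table, frame_ms = 10, seed = 1L) {
  if (!is.numeric(frame_ms) || frame_ms <= 0)
    stop("`frame_ms` must be positive", call. = FALSE)
  span <- max(word_table$onset_ms + word_table$duration_ms)
  n_frames <- ceiling(span / frame_ms)
  time_ms <- (seq_len(n_frames) - 1) * frame_ms
  with_seed(seed, {
    rms <- rep(0.01, n_frames)
    f0 <- rep(80, n_frames)
    peak_rms <- stats::runif(nrow(word_table), 0.1, 0.4)
    peak_f0 <- stats::runif(nrow(word_table), 250, 400)
    true_rms <- true_f0 <- rep(NA_real_, nrow(word_table))
    for (w in seq_len(nrow(word_table))) {
      on <- word_table$onset_ms[w]
      dur <- word_table$duration_ms[w]
      sel <- which(time_ms >= on & time_ms < on + dur)
      if (length(sel) == 0L) next
      shape <- sin(pi * (time_ms[sel] - on) / dur)^2
      rms[sel] <- pmax(rms[sel], peak_rms[w] * shape)
      f0[sel] <- pmax(f0[sel], peak_f0[w] * shape)
      true_rms[w] <- max(rms[sel])
      true_f0[w] <- max(f0[sel])
    }
    list(frames = data.frame(time_ms = time_ms, rms = rms, f0 = f0),
         ground_truth = data.frame(word_id = word_table$word_id,
                                   sim_true_peak_rms = true_rms,
                                   sim_true_peak_f0 = true_f0,
                                   stringsAsFactors = FALSE))
  })
}

#' Simulate a rater-by-sentence ratings matrix
#'
#' `rating(r, s) = latent(s) + noise(r, s)` with `latent ~ N(0,
#' signal_sd^2)` and `noise ~ N(0, noise_sd^2)`.  The latent sentence
#' values are attached as attribute `"latent"` for test oracles.
#'
#' @param n_raters,n_sentences Matrix dimensions.
#' @param signal_sd,noise_sd SDs of shared signal and rater noise.
#' @param seed Integer seed.
#' @return Numeric matrix raters x sentences.
#' @export
simulate_ratings <- function(n_raters, n_sentences, signal_sd = 1,
                             noise_sd = 1, seed = 1L) {
  stopifnot(is_count(n_raters), is_count(n_sentences))
  with_seed(seed, {
    latent <- stats::rnorm(n_sentences, sd = signal_sd)
    eps <- matrix(stats::rnorm(n_raters * n_sentences, sd = noise_sd),
                  n_raters, n_sentences)
    m <- sweep(eps, 2L, latent, "+")
    dimnames(m) <- list(paste0("rater", seq_len(n_raters)),
                        paste0("s", seq_len(n_sentences)))
    attr(m, "latent") <- latent
    m
  })
}

#' Simulate a per-layer embedding set
#'
#' Class means are separated by `class_separation` along one direction and
#' contexts are offset by `context_shift` along an orthogonal direction;
#' an optional word-position confound (`position_shift`) loads on a third
#' direction.  In the two-word context the position flag is confounded
#' with class (nouns are the first token, phrase nouns the second); in the
#' naturalistic context positions are balanced within class.
#'
#' @param n_items_per_class_per_context Items per (class, context) cell.
#' @param dim Embedding dimensionality (>= 3).
#' @param class_separation,context_shift,position_shift Mean offsets in
#'   noise-SD units along three orthogonal directions.
#' @param n_layers Number of layers (independent noise per layer).
#' @param noise_sd Isotropic noise SD.
#' @param seed Integer seed.
#' @return An `embedding_set`: `values` (layers x items x dim) and `meta`
#'   (data.frame `class`, `context`, `word_position`).
#' @export
simulate_embeddings <- function(n_items_per_class_per_context, dim = 16L,
                                class_separation = 2, context_shift = 0,
                                position_shift = 0, n_layers = 3L,
                                noise_sd = 1, seed = 1L) {
  stopifnot(is_count(n_items_per_class_per_context), is_count(dim, 3L),
            is_count(n_layers))
  n <- as.integer(n_items_per_class_per_context)
  cells <- expand.grid(class = c("noun", "phrase"),
                       context = c("two_word", "naturalistic"),
                       stringsAsFactors = FALSE)
  meta <- cells[rep(seq_len(nrow(cells)), each = n), ]
  rownames(meta) <- NULL
  meta$word_position <- ifelse(
    meta$context == "two_word",
    ifelse(meta$class == "noun", "first", "second"),
    rep_len(c("first", "second"), nrow(meta)))
  n_items <- nrow(meta)
  mu <- matrix(0, n_items, dim)
  mu[, 1L] <- ifelse(meta$class == "phrase", 1, -1) * class_separation / 2
  mu[, 2L] <- ifelse(meta$context == "naturalistic", 1, -1) *
    context_shift / 2
  mu[, 3L] <- ifelse(meta$word_position == "second", 1, -1) *
    position_shift / 2
  values <- with_seed(seed, {
    arr <- array(stats::rnorm(n_layers * n_items * dim, sd = noise_sd),
                 dim = c(n_layers, n_items, dim))
    for (l in seq_len(n_layers)) arr[l, , ] <- arr[l, , ] + mu
    arr
  })
  structure(list(values = values, meta = meta), class = "embedding_set")
}
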