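# The binary feed-forward classifier: one hidden layer with two logistic
# units, fit by full-batch BFGS (nnet), deterministic given (data, seed).

#' Classifier specification
#'
#' One hidden layer of `hidden_units` logistic units, logistic output with
#' cross-entropy loss, full-batch quasi-Newton (BFGS) optimization with at
#' most `max_iter` iterations and relative convergence tolerance `reltol`.
#' Initial weights are drawn uniformly on `[-0.5, 0.5]` from `seed`, so
#' training is a pure function of (data, spec).
#'
#' @param hidden_units Hidden units (default 2).
#' @param max_iter Iteration cap for BFGS (default 500).
#' @param reltol Relative convergence tolerance (default 1e-5).
#' @param seed Integer seed fixing the weight initialization.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(hidden_units = 2L, max_iter = 500L,
                            reltol = 1e-5, seed = 1L) {
  if (!is_count(hidden_units, 1L))
    stop("`hidden_units` must be >= 1", call. = FALSE)
  structure(list(hidden_units = as.integer(hidden_units),
                 max_iter = as.integer(max_iter),
                 reltol = as.numeric(reltol),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Initial weight vector for a p-input network, fixed by spec$seed.
init_weights <- function(p, spec) {
  nwts <- (p + 1L) * spec$hidden_units + (spec$hidden_units + 1L)
  with_seed(spec$seed, stats::runif(nwts, -0.5, 0.5))
}

# Bare fitting path shared by fit_classifier and the searchlight loop:
# x numeric matrix, y01 0/1 vector, Wts precomputed initial weights.
ffnn_fit_raw <- function(x, y01, spec, Wts) {
  nnet::nnet(x, y01, size = spec$hidden_units, Wts = Wts,
             entropy = TRUE, maxit = spec$max_iter,
             reltol = spec$reltol, trace = FALSE)
}

#' Fit the feed-forward classifier
#'
#' @param features Numeric matrix, items x dims.
#' @param labels Binary labels (factor or character); the first factor
#'   level (alphabetically `"noun"` before `"phrase"`) is the negative
#'   class.
#' @param spec A [classifier_spec()].
#' @return An `ffnn_classifier` with a [predict()] method returning a
#'   factor of labels.  Predicted probability exactly 0.5 resolves to the
#'   negative (noun) class.
#' @export
fit_classifier <- function(features, labels, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  if (!all(is.finite(features)))
    stop("`features` must be finite", call. = FALSE)
  labels <- as.factor(as.character(labels))
  if (nlevels(labels) != 2L)
    stop("training labels must contain exactly two classes; got: ",
         paste(levels(labels), collapse = ", "), call. = FALSE)
  if (any(table(labels) < 2L))
    stop("need at least 2 items per class", call. = FALSE)
  if (nrow(features) != length(labels))
    stop("feature rows and labels disagree", call. = FALSE)
  y01 <- as.numeric(labels == levels(labels)[2L])
  net <- ffnn_fit_raw(features, y01, spec, init_weights(ncol(features), spec))
  structure(list(net = net, levels = levels(labels), spec = spec),
            class = "ffnn_classifier")
}

#' @export
predict.ffnn_classifier <- function(object, newdata, ...) {
  p <- as.vector(stats::predict(object$net, as.matrix(newdata)))
  # ties at exactly 0.5 resolve to the negative (noun) class
  factor(ifelse(p > 0.5, object$levels[2L], object$levels[1L]),
         levels = object$levels)
}

#' @export
print.ffnn_classifier <- function(x, ...) {
  cat("<ffnn_classifier>", x$spec$hidden_units, "hidden unit(s), classes:",
      paste(x$levels, collapse = " vs "), "\n")
  invisible(x)
}
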