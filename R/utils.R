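# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded internal
#' draws (classifier initialization, synthetic data) never perturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit string hash (polynomial rolling hash); used to derive
# per-subject / per-stage seeds from one master seed.
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (cp in utf8ToInt(x)) h <- (h * 131 + cp) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible 31-bit sub-seed
#'
#' Seeds are derived hierarchically from a single master seed by XOR-ing
#' with a hash of a context string (subject, paradigm, stage), so single
#' stages can be rerun in isolation with identical draws.
#'
#' @param master_seed Integer master seed.
#' @param ... Character/numeric context components (e.g. subject id,
#'   paradigm tag).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  as.integer(bitwXor(as.integer(master_seed %% 2147483647),
                     hash_string(key)) %% 2147483647)
}

# Column z-scoring with n-1 SD; zero-variance columns either error (named)
# or are left centered, depending on `on_zero_sd`.
zscore_matrix <- function(x, on_zero_sd = c("error", "center"), names = NULL) {
  on_zero_sd <- match.arg(on_zero_sd)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  bad <- sdv <= 0 | !is.finite(sdv)
  if (any(bad)) {
    if (on_zero_sd == "error") {
      nm <- if (!is.null(names)) names[bad] else which(bad)
      stop("zero-variance column(s): ", paste(nm, collapse = ", "),
           call. = FALSE)
    }
    sdv[bad] <- 1
  }
  sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write/read a table as tab-separated text with a one-line header
#'
#' @param table A data.frame.
#' @param path File path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= min
}
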