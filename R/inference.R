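# Group-level statistics: mass-univariate one-sample t-tests against
# chance, TFCE with sign-flip max-statistic permutation over the
# source x time graph, and 2-D cluster-mass permutation for TGM matrices.

#' TFCE parameters
#'
#' Exponents default to the method's standard `E = 0.5`, `H = 2`.  The
#' integration step `dh` defaults to `max(t)/100` with a floor of 0.05
#' t-units, computed once from the observed map and reused for every
#' permutation.
#'
#' @param E Extent exponent.
#' @param H Height exponent.
#' @param dh Threshold step in t-units (`NULL` = automatic).
#' @param n_permutations Number of sign-flip permutations (>= 100).
#' @param seed Integer seed for the flip draws.
#' @return A `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, n_permutations = 1000L,
                        seed = 1L) {
  if (!is.null(dh) && dh <= 0) stop("`dh` must be positive", call. = FALSE)
  if (!is_count(n_permutations, 100L))
    stop("`n_permutations` must be >= 100", call. = FALSE)
  structure(list(E = E, H = H, dh = dh,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "tfce_params")
}

# Stack per-subject maps (accuracy_map / tgm_matrix / plain matrices) into
# subjects x cells, row-major cell order (as.vector(t(values))).
stack_maps <- function(maps) {
  vals <- lapply(maps, function(m) {
    v <- if (inherits(m, "accuracy_map") || inherits(m, "tgm_matrix"))
      m$values else m
    as.vector(t(as.matrix(v)))
  })
  d <- dim(if (inherits(maps[[1L]], "accuracy_map") ||
               inherits(maps[[1L]], "tgm_matrix"))
    as.matrix(maps[[1L]]$values) else as.matrix(maps[[1L]]))
  if (any(vapply(vals, length, integer(1)) != d[1] * d[2]))
    stop("per-subject maps have mismatched dimensions", call. = FALSE)
  list(mat = do.call(rbind, vals), dims = d)
}

unflatten <- function(v, dims) matrix(v, dims[1], dims[2], byrow = TRUE)

#' One-sample t-map against chance
#'
#' Per cell, `t = (mean - popmean) / (sd / sqrt(n))` across subjects, with
#' the n-1 SD.  Zero-variance cells are reported as `+Inf`/`-Inf`
#' sentinels; their count is attached and a warning raised.
#'
#' @param per_subject_maps List of `accuracy_map`s (or matrices) with
#'   aligned dimensions; >= 2 subjects.
#' @param popmean Chance level subtracted (default 0.5).
#' @param tail Tail tag, `"greater"` (above-chance only).
#' @return A `t_map`: `t` (matrix), `df`, `popmean`, `n_infinite`.
#' @export
one_sample_t <- function(per_subject_maps, popmean = 0.5,
                         tail = "greater") {
  if (length(per_subject_maps) < 2L)
    stop("need >= 2 subjects", call. = FALSE)
  st <- stack_maps(per_subject_maps)
  n <- nrow(st$mat)
  mu <- colMeans(st$mat) - popmean
  sdv <- apply(st$mat, 2L, stats::sd)
  t <- ifelse(sdv > 0, mu / (sdv / sqrt(n)),
              ifelse(mu == 0, 0, sign(mu) * Inf))
  n_inf <- sum(!is.finite(t))
  if (n_inf > 0L)
    warning(n_inf, " cell(s) had zero across-subject variance; ",
            "t reported as +/-Inf sentinel")
  structure(list(t = unflatten(t, st$dims), df = n - 1L,
                 popmean = popmean, tail = tail, n_infinite = n_inf),
            class = "t_map")
}

tfce_dh <- function(tvals, params) {
  params$dh %||% max(max(tvals, 0) / 100, 0.05)
}

#' Threshold-free cluster enhancement of a t-map
#'
#' `TFCE(v) = sum over h = dh, 2dh, ... <= t(v) of extent_h(v)^E * h^H *
#' dh`, where `extent_h(v)` is the size of the connected component
#' containing `v` among cells with `t >= h`.  Negative t contributes 0
#' (one-tailed).  If `dh` exceeds the map maximum the result is all-zero
#' with a warning.
#'
#' @param tmap A `t_map` or numeric matrix of t-values.
#' @param adjacency An `adjacency` covering all cells (see
#'   [spatiotemporal_adjacency()], [grid_adjacency()]).
#' @param params A [tfce_params()].
#' @return Numeric matrix of TFCE scores, same shape as the input.
#' @export
tfce_transform <- function(tmap, adjacency, params = tfce_params()) {
  stopifnot(inherits(adjacency, "adjacency"))
  values <- if (inherits(tmap, "t_map")) tmap$t else as.matrix(tmap)
  v <- as.vector(t(values))
  v[!is.finite(v)] <- sign(v[!is.finite(v)]) * 100
  if (length(v) != adjacency$n_nodes)
    stop("t-map size does not match adjacency node count", call. = FALSE)
  dh <- tfce_dh(v, params)
  if (dh > max(v, 0)) {
    warning("`dh` exceeds the map maximum; TFCE map is all zero")
    return(values * 0)
  }
  out <- cpp_tfce(v, adjacency$edges, adjacency$n_nodes,
                  params$E, params$H, dh)
  unflatten(out, dim(values))
}

# Sign-flip matrices: Monte-Carlo draws, or exhaustive enumeration of all
# 2^n vectors when that is no larger than the requested count.
make_flips <- function(n_subjects, n_permutations, seed) {
  if (2^n_subjects <= n_permutations) {
    warning("2^", n_subjects, " <= ", n_permutations,
            " permutations requested; enumerating all sign flips exactly")
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n_subjects)))
    dimnames(flips) <- NULL
    list(flips = flips, exact = TRUE)
  } else {
    flips <- with_seed(seed, matrix(sample(c(-1, 1),
                                           n_permutations * n_subjects,
                                           replace = TRUE),
                                    n_permutations, n_subjects))
    list(flips = flips, exact = FALSE)
  }
}

perm_p <- function(obs, null_max, exact) {
  if (exact) vapply(obs, function(o) mean(null_max >= o), numeric(1))
  else vapply(obs, function(o) (1 + sum(null_max >= o)) /
                (length(null_max) + 1), numeric(1))
}

new_cluster_result <- function(nodes, adjacency, t_flat, p, method,
                               time_ms = NULL) {
  if (identical(adjacency$kind, "spatiotemporal")) {
    nt <- adjacency$n_times
    pos <- (nodes - 1L) %/% nt + 1L
    tix <- (nodes - 1L) %% nt + 1L
    vertices <- sort(unique(adjacency$mask_vertices[pos]))
    tms <- if (!is.null(time_ms)) sort(unique(time_ms[tix])) else
      sort(unique(tix))
    structure(list(nodes = nodes, vertices = vertices, times_ms = tms,
                   extent_cells = length(nodes),
                   extent_sources = length(vertices),
                   extent_timepoints = length(tms),
                   peak_t = max(t_flat[nodes]),
                   mass = sum(t_flat[nodes]),
                   p = p, method = method),
              class = "cluster_result")
  } else {
    nc <- adjacency$n_cols
    r <- (nodes - 1L) %/% nc + 1L
    c <- (nodes - 1L) %% nc + 1L
    structure(list(nodes = nodes, train_idx = sort(unique(r)),
                   test_idx = sort(unique(c)),
                   extent_cells = length(nodes),
                   peak_t = max(t_flat[nodes]),
                   mass = sum(t_flat[nodes]),
                   p = p, method = method),
              class = "cluster_result")
  }
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", x$method, "- extent", x$extent_cells, "cells")
  if (!is.null(x$extent_sources))
    cat(" (", x$extent_sources, " sources, ", x$extent_timepoints,
        " timepoints)", sep = "")
  cat(", peak t =", round(x$peak_t, 2), ", mass =", round(x$mass, 1),
      ", p =", signif(x$p, 3), "\n")
  invisible(x)
}

#' Sign-flip max-statistic TFCE permutation test
#'
#' Builds the null distribution as the max over cells of the TFCE map of
#' sign-flipped subject deviations from chance (one flip vector per
#' permutation), yielding family-wise corrected p-values
#' `p(v) = (1 + #\{perm max >= TFCE(v)\}) / (n_perm + 1)`.  When
#' `2^n_subjects` does not exceed the requested permutation count, all
#' flips are enumerated exactly instead.  Significant clusters are the
#' connected components of `{p <= alpha}` under the supplied adjacency.
#'
#' @param per_subject_maps List of aligned `accuracy_map`s (or matrices).
#' @param adjacency An `adjacency` over the map cells.
#' @param params A [tfce_params()].
#' @param alpha Cluster-forming significance level (default 0.05).
#' @param popmean Chance level (default 0.5).
#' @return List with `t_map`, `tfce_map`, `p_map` (corrected, matrix),
#'   `clusters` (list of `cluster_result`), `null_max`, `exact`.
#' @export
sign_flip_permutation <- function(per_subject_maps, adjacency,
                                  params = tfce_params(), alpha = 0.05,
                                  popmean = 0.5) {
  stopifnot(inherits(adjacency, "adjacency"))
  n_sub <- length(per_subject_maps)
  if (n_sub < 2L) stop("need >= 2 subjects", call. = FALSE)
  if (n_sub < 5L)
    warning("fewer than 5 subjects; permutation resolution is coarse")
  st <- stack_maps(per_subject_maps)
  if (ncol(st$mat) != adjacency$n_nodes)
    stop("map size does not match adjacency node count", call. = FALSE)
  dev <- st$mat - popmean

  n <- nrow(dev)
  mu <- colMeans(dev)
  sdv <- apply(dev, 2L, stats::sd)
  t_obs <- ifelse(sdv > 0, mu / (sdv / sqrt(n)),
                  ifelse(mu == 0, 0, sign(mu) * 100))
  dh <- tfce_dh(t_obs, params)

  fl <- make_flips(n_sub, params$n_permutations, params$seed)
  res <- cpp_tfce_signflip(dev, fl$flips, adjacency$edges,
                           params$E, params$H, dh)
  p_flat <- perm_p(res$obs_tfce, res$null_max, fl$exact)

  sig <- p_flat <= alpha
  clusters <- list()
  if (any(sig)) {
    labels <- cpp_components(adjacency$n_nodes, adjacency$edges, sig)
    m1 <- per_subject_maps[[1L]]
    time_ms <- if (inherits(m1, "accuracy_map")) m1$time_ms
               else attr(m1, "time_ms")
    for (lb in sort(unique(labels[labels > 0L]))) {
      nodes <- which(labels == lb)
      clusters[[length(clusters) + 1L]] <-
        new_cluster_result(nodes, adjacency, res$obs_t,
                           p = min(p_flat[nodes]), method = "tfce",
                           time_ms = time_ms)
    }
    clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "p"))]
  }

  list(t_map = structure(list(t = unflatten(res$obs_t, st$dims),
                              df = n_sub - 1L, popmean = popmean,
                              tail = "greater", n_infinite = 0L),
                         class = "t_map"),
       tfce_map = unflatten(res$obs_tfce, st$dims),
       p_map = unflatten(p_flat, st$dims),
       clusters = clusters,
       null_max = res$null_max,
       exact = fl$exact)
}

#' 2-D cluster-mass permutation test for TGM matrices
#'
#' Cell-level one-tailed t against chance; cluster-forming threshold is
#' the upper `threshold_p` t-quantile at `df = n - 1`; clusters are
#' 4-connected components above threshold, with mass = summed t; the null
#' is the max cluster mass under subject sign flips.
#'
#' @param per_subject_tgms List of aligned `tgm_matrix` objects (or
#'   matrices); >= 2 subjects.
#' @param threshold_p Cluster-forming p (default 0.05).
#' @param n_permutations Number of sign flips.
#' @param seed Integer seed.
#' @param alpha Significance level used to flag clusters.
#' @param popmean Chance level (default 0.5).
#' @return List with `t_map`, `clusters` (all suprathreshold clusters,
#'   each with corrected `p`), `significant` (those with `p <= alpha`),
#'   `threshold_t`, `null_max`, `exact`.
#' @export
cluster_mass_permutation_2d <- function(per_subject_tgms,
                                        threshold_p = 0.05,
                                        n_permutations = 1000L,
                                        seed = 1L, alpha = 0.05,
                                        popmean = 0.5) {
  n_sub <- length(per_subject_tgms)
  if (n_sub < 2L)
    stop("need >= 2 subjects for the cluster-mass permutation test",
         call. = FALSE)
  st <- stack_maps(per_subject_tgms)
  dev <- st$mat - popmean
  adjacency <- grid_adjacency(st$dims[1], st$dims[2])
  thr <- stats::qt(1 - threshold_p, df = n_sub - 1L)

  fl <- make_flips(n_sub, n_permutations, seed)
  res <- cpp_cluster_mass_signflip(dev, fl$flips, adjacency$edges, thr)

  sig <- res$obs_t >= thr
  clusters <- list()
  if (any(sig)) {
    labels <- cpp_components(adjacency$n_nodes, adjacency$edges, sig)
    for (lb in sort(unique(labels[labels > 0L]))) {
      nodes <- which(labels == lb)
      mass <- sum(res$obs_t[nodes])
      p <- perm_p(mass, res$null_max, fl$exact)
      cl <- new_cluster_result(nodes, adjacency, res$obs_t, p = p,
                               method = "cluster_mass")
      tg1 <- per_subject_tgms[[1L]]
      if (inherits(tg1, "tgm_matrix")) {
        cl$train_window_ms <- range(tg1$train_time_ms[cl$train_idx])
        cl$test_window_ms <- range(tg1$test_time_ms[cl$test_idx])
      }
      clusters[[length(clusters) + 1L]] <- cl
    }
    clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "p"))]
  }
  list(t_map = structure(list(t = unflatten(res$obs_t, st$dims),
                              df = n_sub - 1L, popmean = popmean,
                              tail = "greater", n_infinite = 0L),
                         class = "t_map"),
       clusters = clusters,
       significant = Filter(function(cl) cl$p <= alpha, clusters),
       threshold_t = thr,
       null_max = res$null_max,
       exact = fl$exact)
}

#' Serialize cluster results to JSON
#'
#' @param clusters List of `cluster_result`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(clusters, path) {
  obj <- lapply(clusters, function(cl) {
    keep <- setdiff(names(cl), "nodes")
    c(cl[keep], list(nodes = as.integer(cl$nodes)))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
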