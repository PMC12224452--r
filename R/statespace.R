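# Classical multidimensional scaling of cluster-restricted neural data
# into 2-D, with per-condition temporal trajectories and distance
# timecourses.

#' Classical (Torgerson) MDS with canonical orientation
#'
#' Double-centered Gram eigendecomposition of squared Euclidean distances
#' (via [stats::cmdscale()]), keeping the top `out_dim` nonnegative
#' eigenpairs.  The embedding is deterministic up to reflection; each
#' output axis is canonicalized so its largest-magnitude coordinate is
#' positive.  If fewer than `out_dim` positive eigenvalues exist the
#' remaining axes are zero-padded with a warning.
#'
#' @param x Numeric matrix, items x dims (>= 3 items, finite).
#' @param out_dim Output dimensionality (default 2).
#' @return Items x `out_dim` coordinate matrix, centered at the origin.
#' @export
classical_mds <- function(x, out_dim = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need >= 3 items", call. = FALSE)
  if (!all(is.finite(x))) stop("`x` must be finite", call. = FALSE)
  fit <- suppressWarnings(
    stats::cmdscale(stats::dist(x), k = out_dim, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  # drop axes whose eigenvalue is zero at machine precision (degenerate
  # configurations), then pad back with exact zeros
  tol <- 1e-8 * max(fit$eig, 0)
  keep <- which(fit$eig[seq_len(ncol(pts))] > tol)
  pts <- pts[, keep, drop = FALSE]
  if (ncol(pts) < out_dim) {
    warning("fewer than ", out_dim,
            " positive eigenvalues; padding with zeros")
    pts <- cbind(pts, matrix(0, nrow(x), out_dim - ncol(pts)))
  }
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  unname(pts)
}

#' Condition trajectories in neural state space
#'
#' Per decoded timepoint, the phrase- and noun-condition mean feature
#' vectors over the cluster's sources are embedded jointly by classical
#' MDS into 2-D, giving one trajectory per condition; the distance
#' timecourse is the per-timepoint distance between the condition means,
#' reported both in the embedded plane and in the full feature space
#' (2-D truncation can distort distances).
#'
#' @param epochs An `epoch_set`.
#' @param cluster A spatiotemporal `cluster_result` (or a list with
#'   `source_set` as from [restrict_to_cluster()]).
#' @return A `statespace_result`: `coords` (data.frame `condition`,
#'   `time_ms`, `dim1`, `dim2`), `distance_timecourse` (data.frame
#'   `time_ms`, `dist_embedded`, `dist_full`).
#' @export
condition_trajectories <- function(epochs, cluster) {
  stopifnot(inherits(epochs, "epoch_set"))
  vertices <- if (inherits(cluster, "cluster_result")) cluster$vertices
              else cluster$source_set %||% cluster$vertices
  if (is.null(vertices) || length(vertices) == 0L)
    stop("cluster is empty", call. = FALSE)
  pos <- match(vertices, epochs$vertices)
  if (anyNA(pos))
    stop("cluster vertices absent from the epoch set", call. = FALSE)
  for (cond in c("noun", "phrase"))
    if (sum(epochs$labels == cond) == 0L)
      stop("condition '", cond, "' has no epochs", call. = FALSE)

  n_t <- length(epochs$time_ms)
  cond_mean <- function(cond) {
    sel <- epochs$labels == cond
    t(vapply(seq_len(n_t), function(t)
      colMeans(epochs$data[sel, pos, t, drop = FALSE][, , 1L, drop = FALSE]),
      numeric(length(pos))))
  }
  P <- cond_mean("phrase")   # times x sources
  N <- cond_mean("noun")
  emb <- classical_mds(rbind(P, N), out_dim = 2L)
  eP <- emb[seq_len(n_t), , drop = FALSE]
  eN <- emb[n_t + seq_len(n_t), , drop = FALSE]

  coords <- data.frame(
    condition = rep(c("phrase", "noun"), each = n_t),
    time_ms = rep(epochs$time_ms, 2L),
    dim1 = c(eP[, 1L], eN[, 1L]),
    dim2 = c(eP[, 2L], eN[, 2L]))
  dtc <- data.frame(
    time_ms = epochs$time_ms,
    dist_embedded = sqrt(rowSums((eP - eN)^2)),
    dist_full = sqrt(rowSums((P - N)^2)))
  structure(list(coords = coords, distance_timecourse = dtc,
                 vertices = vertices),
            class = "statespace_result")
}

#' @export
print.statespace_result <- function(x, ...) {
  cat("<statespace_result>", length(unique(x$coords$time_ms)),
      "timepoints over", length(x$vertices), "sources; peak distance",
      round(max(x$distance_timecourse$dist_full), 3), "at",
      x$distance_timecourse$time_ms[
        which.max(x$distance_timecourse$dist_full)], "ms\n")
  invisible(x)
}
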