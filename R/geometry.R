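# Source-space geometry: icosahedral meshes, region labels, language masks,
# searchlight neighborhoods and spatiotemporal adjacency for cluster
# inference.

#' Build an icosahedral source-space mesh
#'
#' Constructs a level-`level` icosphere by recursive edge-midpoint
#' subdivision of a regular icosahedron, with every vertex projected to the
#' unit sphere.  A level-k icosphere has `10 * 4^k + 2` vertices; level 4
#' gives the conventional 2562 source points used for one hemisphere of a
#' cortical source space.
#'
#' Vertex ordering is deterministic: the 12 icosahedron vertices first, then
#' edge midpoints in order of first appearance at each subdivision pass.
#'
#' @param level Non-negative integer subdivision level (at most 6, to guard
#'   against memory blow-up).
#' @return A `source_mesh` object: list with `level`, `coords` (n x 3 unit
#'   vectors), `edges` (m x 2, ascending vertex pairs), `faces`,
#'   `region` (per-vertex label, initially `"outside_mask"`), and
#'   `hemisphere` (per-vertex tag).
#' @examples
#' mesh <- build_icosphere(2)
#' nrow(mesh$coords)  # 162
#' @export
build_icosphere <- function(level) {
  if (!is_count(level, min = 0L))
    stop("`level` must be a single non-negative integer", call. = FALSE)
  if (level > 6L)
    stop("`level` must be <= 6 (vertex count grows as 10*4^level + 2)",
         call. = FALSE)
  level <- as.integer(level)

  phi <- (1 + sqrt(5)) / 2
  coords <- matrix(c(
    -1,  phi, 0,    1,  phi, 0,   -1, -phi, 0,    1, -phi, 0,
     0, -1,  phi,   0,  1,  phi,   0, -1, -phi,   0,  1, -phi,
     phi, 0, -1,    phi, 0,  1,   -phi, 0, -1,   -phi, 0,  1),
    ncol = 3L, byrow = TRUE)
  coords <- coords / sqrt(rowSums(coords^2))
  faces <- matrix(c(
    1, 12, 6,   1, 6, 2,    1, 2, 8,    1, 8, 11,   1, 11, 12,
    2, 6, 10,   6, 12, 5,   12, 11, 3,  11, 8, 7,   8, 2, 9,
    4, 10, 5,   4, 5, 3,    4, 3, 7,    4, 7, 9,    4, 9, 10,
    5, 10, 6,   3, 5, 12,   7, 3, 11,   9, 7, 8,    10, 9, 2),
    ncol = 3L, byrow = TRUE)

  for (l in seq_len(level)) {
    nf <- nrow(faces)
    e_all <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)],
                   faces[, c(3L, 1L)])
    lo <- pmin(e_all[, 1L], e_all[, 2L])
    hi <- pmax(e_all[, 1L], e_all[, 2L])
    key <- lo * 2^26 + hi           # exact in doubles for < 2^26 vertices
    ukey <- unique(key)             # first-appearance order: deterministic
    mid_of <- match(key, ukey) + nrow(coords)
    first <- match(ukey, key)
    mids <- (coords[lo[first], , drop = FALSE] +
             coords[hi[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    coords <- rbind(coords, mids)
    m12 <- mid_of[seq_len(nf)]
    m23 <- mid_of[nf + seq_len(nf)]
    m31 <- mid_of[2L * nf + seq_len(nf)]
    faces <- rbind(cbind(faces[, 1L], m12, m31),
                   cbind(faces[, 2L], m23, m12),
                   cbind(faces[, 3L], m31, m23),
                   cbind(m12, m23, m31))
  }

  e_all <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  lo <- pmin(e_all[, 1L], e_all[, 2L])
  hi <- pmax(e_all[, 1L], e_all[, 2L])
  keep <- !duplicated(lo * 2^26 + hi)
  edges <- cbind(lo[keep], hi[keep])
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  storage.mode(faces) <- "integer"

  structure(list(
    level = level,
    coords = coords,
    edges = edges,
    faces = faces,
    region = rep("outside_mask", nrow(coords)),
    hemisphere = rep("lh", nrow(coords))
  ), class = "source_mesh")
}

#' @export
print.source_mesh <- function(x, ...) {
  cat("<source_mesh> level", x$level, "-", nrow(x$coords), "vertices,",
      nrow(x$edges), "edges\n")
  tab <- table(x$region)
  cat("  regions:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Assign region labels to mesh vertices
#'
#' Labels vertices according to a named specification mapping region names
#' to either explicit vertex index vectors or predicate functions of the
#' coordinate matrix.  Regions must be disjoint; vertices claimed by no
#' region are labeled `"outside_mask"`.
#'
#' @param mesh A `source_mesh`.
#' @param region_spec Named list; each element is an integer vector of
#'   vertex indices or a function `f(coords)` returning a logical vector.
#' @return The mesh with its `region` field replaced.
#' @export
assign_regions <- function(mesh, region_spec) {
  stopifnot(inherits(mesh, "source_mesh"))
  n <- nrow(mesh$coords)
  labels <- rep("outside_mask", n)
  if (length(region_spec) == 0L) {
    mesh$region <- labels
    return(mesh)
  }
  if (is.null(names(region_spec)) || any(!nzchar(names(region_spec))))
    stop("`region_spec` must be a fully named list", call. = FALSE)
  claimed <- logical(n)
  for (nm in names(region_spec)) {
    item <- region_spec[[nm]]
    idx <- if (is.function(item)) {
      flag <- item(mesh$coords)
      if (!is.logical(flag) || length(flag) != n)
        stop("predicate for region '", nm,
             "' must return a logical vector over all vertices",
             call. = FALSE)
      which(flag)
    } else {
      idx <- as.integer(item)
      if (any(idx < 1L | idx > n))
        stop("region '", nm, "' lists vertex indices outside the mesh",
             call. = FALSE)
      idx
    }
    if (any(claimed[idx]))
      stop("region '", nm, "' overlaps a previously assigned region",
           call. = FALSE)
    claimed[idx] <- TRUE
    labels[idx] <- nm
  }
  mesh$region <- labels
  mesh
}

#' Default six-region partition of a hemisphere mesh
#'
#' Partitions the icosphere into six contiguous spherical caps (nearest of
#' six axis directions), named after the regions of a left-lateralized
#' language mask (anterior/middle temporal, inferior frontal, ventromedial
#' prefrontal, angular and supramarginal) so that synthetic results can be
#' summarized in the field's vocabulary.  These are synthetic stand-ins,
#' not anatomical labels.
#'
#' @param mesh A `source_mesh`.
#' @return A named list of vertex index vectors covering all vertices,
#'   suitable for [assign_regions()].
#' @export
default_region_spec <- function(mesh) {
  stopifnot(inherits(mesh, "source_mesh"))
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nms <- c("LATL", "LMTG", "LIFG", "LvmPFC", "LAG", "LSMG")
  sim <- mesh$coords %*% t(dirs)
  nearest <- max.col(sim, ties.method = "first")
  out <- lapply(seq_len(6L), function(i) which(nearest == i))
  names(out) <- nms
  out
}

#' Build a language mask from named regions
#'
#' @param mesh A `source_mesh` with regions assigned.
#' @param region_names Character vector of region names to include.
#' @return A `language_mask`: list with `vertices`, the union of the named
#'   regions' vertex indices in ascending order.
#' @export
make_language_mask <- function(mesh, region_names) {
  stopifnot(inherits(mesh, "source_mesh"))
  region_names <- unique(as.character(region_names))
  known <- unique(mesh$region)
  missing <- setdiff(region_names, known)
  if (length(missing) > 0L)
    stop("unknown region name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  vertices <- sort(which(mesh$region %in% region_names))
  if (length(vertices) == 0L)
    stop("language mask is empty", call. = FALSE)
  structure(list(vertices = vertices, n_mesh = nrow(mesh$coords)),
            class = "language_mask")
}

#' @export
print.language_mask <- function(x, ...) {
  cat("<language_mask>", length(x$vertices), "of", x$n_mesh, "vertices\n")
  invisible(x)
}

#' Searchlight neighborhoods within a mask
#'
#' For every masked vertex, the `k` nearest masked vertices by Euclidean
#' (chord) distance on the mesh coordinates, center included; ties broken
#' by ascending vertex index.  The searchlight "radius of k sources" is a
#' k-member nearest-neighbor set, not a geodesic disc.
#'
#' @param mesh A `source_mesh`.
#' @param mask A `language_mask` on the same mesh.
#' @param k Searchlight size in sources (default 20).
#' @return A `neighborhoods` object: list with `centers` (masked vertex
#'   indices) and `members` (list of member vertex vectors, distance order,
#'   center first), plus a `truncated` flag when `k` exceeded the mask size.
#' @export
searchlight_neighborhoods <- function(mesh, mask, k = 20L) {
  stopifnot(inherits(mesh, "source_mesh"), inherits(mask, "language_mask"))
  if (!is_count(k, min = 1L))
    stop("`k` must be a positive integer", call. = FALSE)
  mv <- mask$vertices
  truncated <- FALSE
  if (k > length(mv)) {
    warning("k = ", k, " exceeds mask size ", length(mv),
            "; neighborhoods truncated to the whole mask")
    truncated <- TRUE
    k <- length(mv)
  }
  dmat <- as.matrix(stats::dist(mesh$coords[mv, , drop = FALSE]))
  members <- lapply(seq_along(mv), function(i) {
    ord <- order(dmat[i, ], mv)   # ties by ascending vertex index
    mv[ord[seq_len(k)]]
  })
  names(members) <- as.character(mv)
  structure(list(centers = mv, members = members, k = as.integer(k),
                 truncated = truncated),
            class = "neighborhoods")
}

# Mask-internal edge list, as positions within mask$vertices (p x 2).
mask_edge_positions <- function(mesh, mask) {
  p1 <- match(mesh$edges[, 1L], mask$vertices)
  p2 <- match(mesh$edges[, 2L], mask$vertices)
  keep <- !is.na(p1) & !is.na(p2)
  cbind(p1[keep], p2[keep])
}

#' Spatiotemporal adjacency over (vertex, timepoint) nodes
#'
#' Node `(v, t)` is adjacent to `(w, t)` iff `{v, w}` is a mesh edge with
#' both ends inside the mask, and to `(v, t±1)`.  Nodes are indexed
#' time-fastest: node of the i-th masked vertex at timepoint t is
#' `(i - 1) * n_times + t`, matching the row-major flattening
#' `as.vector(t(values))` of a `sources x times` map.
#'
#' @param mesh A `source_mesh`.
#' @param mask A `language_mask`.
#' @param n_times Positive integer number of timepoints.
#' @return An `adjacency` object: list with `edges` (undirected pairs,
#'   1-based node ids), `n_nodes`, `mask_vertices`, `n_times`.
#' @export
spatiotemporal_adjacency <- function(mesh, mask, n_times) {
  stopifnot(inherits(mesh, "source_mesh"), inherits(mask, "language_mask"))
  if (!is_count(n_times, min = 1L))
    stop("`n_times` must be a positive integer", call. = FALSE)
  n_times <- as.integer(n_times)
  mv <- mask$vertices
  n_mask <- length(mv)
  me <- mask_edge_positions(mesh, mask)
  node <- function(pos, t) (pos - 1L) * n_times + t

  spat <- if (nrow(me) > 0L) {
    t_rep <- rep(seq_len(n_times), each = nrow(me))
    cbind(node(rep(me[, 1L], times = n_times), t_rep),
          node(rep(me[, 2L], times = n_times), t_rep))
  } else matrix(integer(0), 0L, 2L)
  temp <- if (n_times > 1L) {
    pos_rep <- rep(seq_len(n_mask), each = n_times - 1L)
    t_rep <- rep(seq_len(n_times - 1L), times = n_mask)
    cbind(node(pos_rep, t_rep), node(pos_rep, t_rep + 1L))
  } else matrix(integer(0), 0L, 2L)

  edges <- rbind(spat, temp)
  storage.mode(edges) <- "integer"
  structure(list(edges = edges, n_nodes = n_mask * n_times,
                 mask_vertices = mv, n_times = n_times,
                 kind = "spatiotemporal"),
            class = "adjacency")
}

#' 4-connected grid adjacency (for TGM matrices)
#'
#' @param n_rows,n_cols Grid dimensions (train times x test times).
#' @return An `adjacency` object over `n_rows * n_cols` nodes, row-major
#'   (node of cell `(r, c)` is `(r - 1) * n_cols + c`).
#' @export
grid_adjacency <- function(n_rows, n_cols) {
  stopifnot(is_count(n_rows), is_count(n_cols))
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  node <- function(r, c) (r - 1L) * n_cols + c
  horiz <- if (n_cols > 1L) {
    r <- rep(seq_len(n_rows), each = n_cols - 1L)
    c <- rep(seq_len(n_cols - 1L), times = n_rows)
    cbind(node(r, c), node(r, c + 1L))
  } else matrix(integer(0), 0L, 2L)
  vert <- if (n_rows > 1L) {
    r <- rep(seq_len(n_rows - 1L), each = n_cols)
    c <- rep(seq_len(n_cols), times = n_rows - 1L)
    cbind(node(r, c), node(r + 1L, c))
  } else matrix(integer(0), 0L, 2L)
  edges <- rbind(horiz, vert)
  storage.mode(edges) <- "integer"
  structure(list(edges = edges, n_nodes = n_rows * n_cols,
                 n_rows = n_rows, n_cols = n_cols, kind = "grid"),
            class = "adjacency")
}

#' Serialize a mesh to JSON
#'
#' Writes `{"level":, "coords":, "edges":, "regions": {name: [indices]}}`.
#'
#' @param mesh A `source_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_json <- function(mesh, path) {
  stopifnot(inherits(mesh, "source_mesh"))
  regions <- split(seq_len(nrow(mesh$coords)), mesh$region)
  obj <- list(level = mesh$level,
              coords = unname(apply(mesh$coords, 1L, as.numeric,
                                    simplify = FALSE)),
              edges = unname(apply(mesh$edges, 1L, as.integer,
                                   simplify = FALSE)),
              regions = regions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mesh from JSON written by [write_mesh_json()]
#' @param path Input file path.
#' @return A `source_mesh`.
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mesh <- build_icosphere(obj$level)
  spec <- lapply(obj$regions, as.integer)
  spec <- spec[setdiff(names(spec), "outside_mask")]
  assign_regions(mesh, spec)
}
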