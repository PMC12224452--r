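# Shared fixtures: tiny geometries, fast classifier specs, and an
# independent TFCE oracle (igraph-based threshold loop) for dual-route
# checks of the compiled implementation.

all_regions <- c("LATL", "LMTG", "LIFG", "LvmPFC", "LAG", "LSMG")

tiny_geometry <- function(level = 0L, regions = all_regions) {
  mesh <- build_icosphere(level)
  mesh <- assign_regions(mesh, default_region_spec(mesh))
  list(mesh = mesh, mask = make_language_mask(mesh, regions))
}

quick_spec <- function(seed = 1L) classifier_spec(max_iter = 200L,
                                                  seed = seed)

# Brute-force TFCE: explicit threshold loop with igraph connected
# components; independent of the compiled union-find sweep.
tfce_oracle <- function(tvals, adjacency, E, H, dh) {
  n <- adjacency$n_nodes
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(adjacency$edges) > 0L)
    g <- igraph::add_edges(g, t(adjacency$edges))
  score <- numeric(n)
  hmax <- max(tvals)
  if (hmax <= 0) return(score)
  for (h in seq(dh, hmax, by = dh)) {
    active <- which(tvals >= h)
    if (length(active) == 0L) break
    sub <- igraph::induced_subgraph(g, active)
    comp <- igraph::components(sub)
    score[active] <- score[active] +
      comp$csize[comp$membership]^E * h^H * dh
  }
  score
}

# Two-class Gaussian clouds in p dimensions, separated along the first axis.
make_clouds <- function(n_per_class, p, separation, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), ncol = p)
  y <- rep(c("noun", "phrase"), each = n_per_class)
  x[y == "phrase", 1L] <- x[y == "phrase", 1L] + separation
  list(x = x, y = factor(y))
}
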