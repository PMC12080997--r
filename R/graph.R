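#' Small-world coefficient of a connectome
#'
#' Binarizes the connectome by keeping the top `density` fraction of
#' positive-z edges (proportional thresholding, so networks of different
#' modalities are compared at equal sparsity), then computes the
#' Humphries-Gurney small-world coefficient
#'
#'   sigma = (C / C_rand) / (L / L_rand) ,
#'
#' where C is the mean nodal clustering coefficient (nodes with fewer than
#' two neighbours contribute zero), L is the characteristic path length on
#' the largest connected component, and the null values are means over
#' `n_rand` degree-preserving double-edge-swap rewirings of the thresholded
#' graph. sigma > 1 indicates small-world organization.
#'
#' @param conn A `connectome` (or symmetric z matrix).
#' @param density Fraction of all unique region pairs retained as edges
#'   (default 0.25). Exactly `ceiling(density * R(R-1)/2)` edges are kept;
#'   ties are broken by fixed region-pair order.
#' @param n_rand Number of rewired null graphs (default 100).
#' @param seed Optional integer seed for the rewiring RNG.
#' @return A `graph_metrics` object: `clustering_C`, `path_length_L`,
#'   `rand_C_mean`, `rand_L_mean`, `sigma`, and the parameters used.
#' @export
small_world_coefficient <- function(conn, density = 0.25, n_rand = 100,
                                    seed = NULL) {
  z <- connectome_z(conn)
  R <- nrow(z)
  if (R < 8L) stop("need at least 8 regions, got ", R)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- z[upper.tri(z)]
  m <- ceiling(density * R * (R - 1) / 2)
  pos <- which(w > 0)
  if (length(pos) < m) {
    stop("only ", length(pos), " positive edges; cannot reach density ",
         density, " (", m, " edges)")
  }
  # fixed tie-break: decreasing z, then row, then column index
  ord <- pos[order(-w[pos], ut[pos, 1], ut[pos, 2])]
  keep <- ord[seq_len(m)]
  g <- igraph::graph_from_edgelist(cbind(ut[keep, 1], ut[keep, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, R - igraph::vcount(g)))
  comp <- igraph::components(g)
  if (max(comp$csize) < 2L) {
    stop("graph fully disconnected after thresholding; try a higher density")
  }
  if (!is.null(seed)) set.seed(seed)
  C <- mean_clustering(g)
  L <- largest_component_path_length(g, comp)
  Cr <- Lr <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
    Cr[i] <- mean_clustering(gr)
    Lr[i] <- largest_component_path_length(gr)
  }
  sigma <- (C / mean(Cr)) / (L / mean(Lr))
  structure(list(clustering_C = C, path_length_L = L,
                 rand_C_mean = mean(Cr), rand_L_mean = mean(Lr),
                 rand_C = Cr, rand_L = Lr, sigma = sigma,
                 params = list(density = density, n_rand = n_rand,
                               seed = seed, n_edges = m)),
            class = "graph_metrics")
}

# mean nodal clustering coefficient; degree < 2 nodes count as zero
mean_clustering <- function(g) {
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  mean(loc)
}

# characteristic path length restricted to the largest connected component
largest_component_path_length <- function(g, comp = NULL) {
  if (is.null(comp)) comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == biggest))
  igraph::mean_distance(sub, directed = FALSE)
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat("<graph_metrics> C = ", round(x$clustering_C, 4),
      ", L = ", round(x$path_length_L, 4),
      ", sigma = ", round(x$sigma, 4),
      " (density ", x$params$density, ", ", x$params$n_rand, " nulls)\n",
      sep = "")
  invisible(x)
}

#' Group-level small-world test
#'
#' One-sample t-test of per-subject small-world coefficients against 1,
#' one-sided (greater), i.e. the test that the cohort is small-world.
#'
#' @param metrics List of `graph_metrics` objects, or a numeric vector of
#'   sigma values.
#' @return List with `mean`, `sd`, `t`, `p`, `n`.
#' @export
group_small_world_test <- function(metrics) {
  sigmas <- if (is.numeric(metrics)) metrics
            else vapply(metrics, function(m) m$sigma, 0)
  if (length(sigmas) < 2L) stop("need at least 2 subjects")
  res <- paired_t(sigmas, mu = 1, alternative = "greater")
  list(mean = mean(sigmas), sd = stats::sd(sigmas),
       t = res$t, p = res$p, n = length(sigmas))
}
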