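#' PCA embedding of samples
#'
#' Samples are observations, genes variables. Count-derived normalized
#' values should be `log1p`-transformed (the default); pre-normalized
#' microarray intensities typically should not. Genes are mean-centered.
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making the embedding fully deterministic.
#'
#' @param m an `ExpressionMatrix`.
#' @param d number of principal components, reduced to the matrix rank with
#'   a warning if larger. Default `min(50, n_samples - 1)`.
#' @param log_transform apply `log1p` before PCA (default `TRUE`).
#' @return An `Embedding`: list with `coords` (samples x d, rownames =
#'   sample IDs), `explained_variance` (component variances) and `d`.
#' @export
pca_embed <- function(m, d = min(50L, ncol(m$values) - 1L),
                      log_transform = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"), d >= 2)
  x <- t(m$values)
  if (log_transform) x <- log1p(x)
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > p$sdev[1] * 1e-12)
  if (d > rank) {
    warning(sprintf("d = %d exceeds data rank %d; using %d components", d, rank, rank))
    d <- rank
  }
  rot <- p$rotation[, seq_len(d), drop = FALSE]
  scores <- p$x[, seq_len(d), drop = FALSE]
  flip <- vapply(seq_len(d), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(scores, 2, flip, "*")
  rownames(scores) <- sample_ids(m)
  structure(list(coords = scores, explained_variance = p$sdev[seq_len(d)]^2,
                 d = d),
            class = "Embedding")
}

# connected-component labels of a boolean adjacency matrix
component_labels <- function(adj) {
  n <- nrow(adj)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    frontier <- i
    lab[i] <- cur
    while (length(frontier)) {
      nbrs <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & lab == 0)
      lab[nbrs] <- cur
      frontier <- nbrs
    }
  }
  lab
}

# smooth-kNN bandwidth: binary search for sigma so that
# sum_j exp(-max(0, d_j - rho)/sigma) = target, UMAP-style.
smooth_knn_sigma <- function(dists, rho, target, n_iter = 64L, tol = 1e-5) {
  lo <- 0; hi <- Inf; mid <- 1
  for (it in seq_len(n_iter)) {
    val <- sum(exp(-pmax(0, dists - rho) / mid))
    if (abs(val - target) < tol) break
    if (val > target) {          # weights too heavy -> shrink sigma
      hi <- mid
      mid <- (lo + hi) / 2
    } else {
      lo <- mid
      mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
    }
  }
  mid
}

#' Fuzzy simplicial nearest-neighbor graph
#'
#' Builds the UMAP-style weighted kNN graph over the embedded samples:
#' exact Euclidean k-nearest neighbors; per-sample directed memberships
#' `w(u,v) = exp(-max(0, dist(u,v) - rho_u) / sigma_u)` where `rho_u` is the
#' distance to the nearest neighbor and `sigma_u` is calibrated by binary
#' search so the memberships sum to `log2(n_neighbors)`; symmetrized by the
#' probabilistic t-conorm `W = A + A' - A o A'`.
#'
#' When the kNN graph falls apart into several connected components (well
#' separated sample clusters), commodities crossing components would all be
#' unreachable; with `ensure_connected = TRUE` (default) the components are
#' joined by their cheapest pairwise bridge edges along a minimum spanning
#' tree over components, each bridge weighted by its smooth-kNN membership.
#' This augmentation is reported via a message and never fires on a graph
#' that is already connected.
#'
#' @param e an `Embedding` from [pca_embed()].
#' @param n_neighbors neighbors per sample, `2 <= k < n_samples`. Cohorts of
#'   a few hundred samples typically use 10-20; small cohorts ~5.
#' @param ensure_connected add MST bridge edges between components.
#' @return A `ConnectivityGraph`: list with `nodes`, `edges`
#'   (data.frame from/to/weight, from < to, weights in (0,1]), `n_neighbors`.
#' @export
fuzzy_graph <- function(e, n_neighbors = 15L, ensure_connected = TRUE) {
  stopifnot(inherits(e, "Embedding"))
  x <- e$coords
  n <- nrow(x)
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  if (n_neighbors >= n) stop("n_neighbors must be < number of samples")
  dm <- as.matrix(stats::dist(x))
  target <- log2(n_neighbors)
  A <- matrix(0, n, n)
  for (u in seq_len(n)) {
    d_u <- dm[u, ]
    ord <- order(d_u)
    nbr <- setdiff(ord, u)[seq_len(n_neighbors)]
    dn <- d_u[nbr]
    rho <- min(dn)
    sigma <- smooth_knn_sigma(dn, rho, target)
    A[u, nbr] <- exp(-pmax(0, dn - rho) / sigma)
  }
  W <- A + t(A) - A * t(A)
  if (ensure_connected) {
    comp <- component_labels(W > 0)
    n_comp <- max(comp)
    if (n_comp > 1) {
      message(sprintf("connectivity graph has %d components; adding MST bridge edges",
                      n_comp))
      # MST over components, edges = cheapest inter-component sample pair
      joined <- comp
      repeat {
        groups <- unique(joined)
        if (length(groups) == 1) break
        g1 <- which(joined == groups[1])
        g2 <- which(joined != groups[1])
        sub <- dm[g1, g2, drop = FALSE]
        hit <- which(sub == min(sub), arr.ind = TRUE)[1, ]
        u <- g1[hit[1]]; v <- g2[hit[2]]
        d_uv <- dm[u, v]
        rho_u <- min(dm[u, -u]); rho_v <- min(dm[v, -v])
        w_uv <- exp(-pmax(0, d_uv - max(rho_u, rho_v)) /
                      smooth_knn_sigma(dm[u, -u][order(dm[u, -u])][seq_len(n_neighbors)],
                                       rho_u, target))
        W[u, v] <- W[v, u] <- max(W[u, v], min(1, w_uv), 1e-3)
        joined[joined == joined[v]] <- joined[u]
      }
    }
  }
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ids <- rownames(x)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges, n_neighbors = n_neighbors),
            class = "ConnectivityGraph")
}

as_igraph <- function(g) {
  stopifnot(inherits(g, "ConnectivityGraph"))
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

#' Disease-state assignment by Leiden clustering
#'
#' Runs Leiden community detection (modularity objective) on the weighted
#' connectivity graph. Cluster IDs are relabeled 0-based in order of first
#' appearance along the node list, so the assignment is reproducible
#' bit-for-bit for a fixed seed.
#'
#' @param g a `ConnectivityGraph`.
#' @param resolution Leiden resolution parameter (default 1).
#' @param seed RNG seed (Leiden refinement is randomized).
#' @return A `StateAssignment`: list with `labels` (named integer vector,
#'   0-based), `n_states`, `resolution`.
#' @export
leiden_states <- function(g, resolution = 1.0, seed = 1L) {
  ig <- as_igraph(g)
  if (igraph::vcount(ig) == 0) stop("empty connectivity graph")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                               weights = igraph::E(ig)$weight,
                               resolution = resolution, n_iterations = 10)
  memb <- igraph::membership(cl)
  memb <- memb[g$nodes]
  relab <- match(memb, unique(memb)) - 1L
  names(relab) <- g$nodes
  structure(list(labels = relab, n_states = length(unique(relab)),
                 resolution = resolution),
            class = "StateAssignment")
}

#' Select the Leiden resolution by silhouette
#'
#' Runs [leiden_states()] over a small resolution grid and returns the
#' assignment whose clusters maximize the mean silhouette width in the
#' embedding (Euclidean distances on the PCA coordinates). A standard way to
#' pick clustering granularity when the number of disease states is unknown;
#' partitions with a single cluster are skipped.
#'
#' @param g a `ConnectivityGraph`.
#' @param e the `Embedding` the graph was built from.
#' @param grid candidate resolutions.
#' @param seed RNG seed passed to [leiden_states()].
#' @return The selected `StateAssignment`, with the chosen resolution in
#'   `$resolution` and its mean silhouette in `$silhouette`.
#' @export
select_resolution <- function(g, e, grid = c(0.3, 0.5, 0.7, 1.0, 1.4),
                              seed = 1L) {
  stopifnot(inherits(e, "Embedding"))
  dm <- stats::dist(e$coords[g$nodes, , drop = FALSE])
  best <- NULL; best_sil <- -Inf
  for (r in grid) {
    st <- leiden_states(g, resolution = r, seed = seed)
    if (st$n_states < 2) next
    sil <- cluster::silhouette(unname(st$labels), dm)
    msil <- mean(sil[, "sil_width"])
    if (msil > best_sil) { best_sil <- msil; best <- st }
  }
  if (is.null(best)) stop("no resolution in the grid produced >= 2 states")
  best$silhouette <- best_sil
  best
}

#' Export helpers for graphs and state assignments
#'
#' @param g a `ConnectivityGraph`.
#' @param path output path.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edges_tsv <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graphml
#' @param states a `StateAssignment`.
#' @export
write_states_tsv <- function(states, path) {
  utils::write.table(data.frame(sample_id = names(states$labels),
                                state = unname(states$labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
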