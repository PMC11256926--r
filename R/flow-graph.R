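#' Directed flow network
#'
#' `flow_graph()` builds a directed arc set from an undirected edge table:
#' each edge contributes two opposite arcs of equal cost.
#' `flow_graph_from_embedding()` derives the edges from a
#' `ConnectivityGraph` and prices every arc by the Euclidean distance
#' between the PCA embeddings of its endpoints (the fuzzy weights define
#' the topology, the embedding defines the costs).
#'
#' @param edges data.frame with columns `from`, `to`, `cost` (undirected;
#'   `cost >= 0`, no self-edges).
#' @param nodes optional node ID vector (default: all endpoint IDs).
#' @return A `FlowGraph`: list with `nodes`, `arcs` (directed data.frame
#'   from/to/cost) and index structures for traversal.
#' @export
flow_graph <- function(edges, nodes = NULL) {
  stopifnot(all(c("from", "to", "cost") %in% names(edges)))
  if (any(edges$cost < 0)) stop("negative arc cost")
  if (any(edges$from == edges$to)) stop("self-edges not allowed")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  arcs <- data.frame(
    from = c(edges$from, edges$to),
    to = c(edges$to, edges$from),
    cost = c(edges$cost, edges$cost),
    stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$from, arcs$to), , drop = FALSE]
  if (anyDuplicated(arcs[c("from", "to")])) stop("duplicated arcs")
  rownames(arcs) <- NULL
  new_flow_graph(nodes, arcs)
}

new_flow_graph <- function(nodes, arcs) {
  from_i <- match(arcs$from, nodes)
  to_i <- match(arcs$to, nodes)
  if (anyNA(from_i) || anyNA(to_i)) stop("arc endpoint not in node set")
  n <- length(nodes)
  structure(list(
    nodes = nodes, arcs = arcs, from_i = from_i, to_i = to_i,
    out_arcs = split(seq_along(from_i), factor(from_i, levels = seq_len(n))),
    in_arcs = split(seq_along(to_i), factor(to_i, levels = seq_len(n)))),
    class = "FlowGraph")
}

#' @rdname flow_graph
#' @param cg a `ConnectivityGraph`.
#' @param e the `Embedding` the graph was built from.
#' @export
flow_graph_from_embedding <- function(cg, e) {
  stopifnot(inherits(cg, "ConnectivityGraph"), inherits(e, "Embedding"))
  x <- e$coords[cg$nodes, , drop = FALSE]
  d <- sqrt(rowSums((x[cg$edges$from, , drop = FALSE] -
                     x[cg$edges$to, , drop = FALSE])^2))
  flow_graph(data.frame(from = cg$edges$from, to = cg$edges$to, cost = d,
                        stringsAsFactors = FALSE),
             nodes = cg$nodes)
}

#' @export
print.FlowGraph <- function(x, ...) {
  cat(sprintf("FlowGraph: %d nodes, %d directed arcs\n",
              length(x$nodes), nrow(x$arcs)))
  invisible(x)
}

# BFS hop distances from node index `src`; `reverse` walks arcs backwards.
bfs_hops <- function(g, src, reverse = FALSE) {
  n <- length(g$nodes)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  adj <- if (reverse) g$in_arcs else g$out_arcs
  nxt_of <- if (reverse) g$from_i else g$to_i
  while (length(frontier)) {
    nbrs <- unique(nxt_of[unlist(adj[frontier], use.names = FALSE)])
    nbrs <- nbrs[is.infinite(dist[nbrs])]
    dist[nbrs] <- dist[frontier[1]] + 1
    frontier <- nbrs
  }
  dist
}

#' Build commodities from patient visit metadata
#'
#' One commodity per consecutive pair of observed visits of each patient:
#' a series a -> b -> c yields the two commodities a->b and b->c. Patients
#' with a single observed visit yield none (reported via a message).
#'
#' @param meta a `SampleMeta` data.frame.
#' @param demand flow demand per commodity (default 1).
#' @return data.frame of class `CommoditySet` with columns `id`, `source`,
#'   `sink`, `demand`, `patient_id`, `transition_rank` (1 = first
#'   transition), ordered by (patient, transition_rank).
#' @export
build_commodities <- function(meta, demand = 1) {
  stopifnot(inherits(meta, "SampleMeta") || is.data.frame(meta))
  meta <- meta[order(meta$patient_id, meta$visit_rank), , drop = FALSE]
  by_pat <- split(meta$sample_id, meta$patient_id)
  singles <- sum(lengths(by_pat) == 1)
  if (singles > 0)
    message(sprintf("%d patient(s) with a single visit yield no commodities", singles))
  rows <- lapply(names(by_pat), function(p) {
    s <- by_pat[[p]]
    if (length(s) < 2) return(NULL)
    data.frame(source = s[-length(s)], sink = s[-1], demand = demand,
               patient_id = p, transition_rank = seq_len(length(s) - 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(source = character(), sink = character(),
                      demand = numeric(), patient_id = character(),
                      transition_rank = integer(), stringsAsFactors = FALSE)
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("CommoditySet", "data.frame")
  out
}

#' Restrict arcs to an l-hop source-sink corridor
#'
#' Returns the arcs that lie on some source-to-sink walk of at most `l`
#' hops: arc (u,v) is kept iff `hop(s,u) + 1 + hop(v,t) <= l`, with hop
#' distances from directed BFS. An empty result means no s->t path of
#' length <= l exists.
#'
#' @param g a `FlowGraph`.
#' @param source,sink node IDs.
#' @param l hop limit, >= 1.
#' @return Integer vector of arc indices into `g$arcs`.
#' @export
restrict_arcs <- function(g, source, sink, l) {
  stopifnot(l >= 1)
  s <- match(source, g$nodes); t <- match(sink, g$nodes)
  if (is.na(s) || is.na(t)) stop("source or sink not in graph")
  ds <- bfs_hops(g, s)
  dt <- bfs_hops(g, t, reverse = TRUE)
  which(ds[g$from_i] + 1 + dt[g$to_i] <= l)
}

#' Partition commodities into reachable and unreachable
#'
#' A commodity is unreachable when its (optionally l-hop-restricted) arc set
#' admits no source-to-sink path. Unreachable commodities must be removed
#' before solving the flow LP.
#'
#' @param commodities a `CommoditySet`.
#' @param g a `FlowGraph`.
#' @param l optional hop limit (as in [restrict_arcs()]); `NULL` =
#'   plain reachability.
#' @return list with `kept` and `dropped` (`dropped` has a `reason` column).
#' @export
drop_unreachable <- function(commodities, g, l = NULL) {
  if (!nrow(commodities)) return(list(kept = commodities, dropped = commodities))
  ok <- vapply(seq_len(nrow(commodities)), function(i) {
    s <- match(commodities$source[i], g$nodes)
    t <- match(commodities$sink[i], g$nodes)
    if (is.na(s) || is.na(t)) return(FALSE)
    d <- bfs_hops(g, s)[t]
    if (is.null(l)) is.finite(d) else d <= l
  }, logical(1))
  dropped <- commodities[!ok, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "unreachable"
  kept <- commodities[ok, , drop = FALSE]
  if (nrow(dropped))
    message(sprintf("dropped %d/%d commodities as unreachable (%.1f%%)",
                    nrow(dropped), nrow(commodities),
                    100 * nrow(dropped) / nrow(commodities)))
  list(kept = kept, dropped = dropped)
}
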