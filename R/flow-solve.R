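#' Capacity configuration for the flow LP
#'
#' @param edge_capacity shared per-arc capacity `C > 0` (default 1; the
#'   smallest value that admits a feasible routing is the usual choice, so
#'   congested cohorts may need 2 or more).
#' @param node_capacity per-node cap `N > 0` on total inbound flow across
#'   commodities, `Inf` to disable (default).
#' @param hop_limit optional corridor limit `l >= 1`: each commodity only
#'   sees arcs on some source-sink walk of at most `l` hops (see
#'   [restrict_arcs()]). `NULL` = no restriction.
#' @return A `CapacityConfig` list.
#' @export
capacity_config <- function(edge_capacity = 1, node_capacity = Inf,
                            hop_limit = NULL) {
  stopifnot(edge_capacity > 0, node_capacity > 0,
            is.null(hop_limit) || hop_limit >= 1)
  structure(list(edge_capacity = edge_capacity, node_capacity = node_capacity,
                 hop_limit = hop_limit),
            class = "CapacityConfig")
}

#' Solve the multi-commodity flow LP
#'
#' Minimizes the total routing cost `U = sum_(u,v) c(u,v) sum_i f_i(u,v)`
#' over fractional per-commodity arc flows `f_i(u,v) in [0,1]` subject to
#' flow conservation (net +D at each commodity's source, -D at its sink, 0
#' elsewhere), the shared edge capacity `sum_i f_i(u,v) <= C`, and — when a
#' finite node capacity is set — the inbound node cap
#' `sum_i sum_u f_i(u,w) <= N`. The integer version of this problem is
#' NP-complete; the fractional relaxation solved here is a polynomial-size
#' LP, and per-commodity paths are recovered by [extract_paths()].
#'
#' @param g a `FlowGraph`.
#' @param commodities a `CommoditySet`; all must be reachable (run
#'   [drop_unreachable()] first).
#' @param cfg a [capacity_config()].
#' @param solver LP backend (see [lp_solve()]).
#' @return A `FlowSolution`: list with `status` ("optimal"/"infeasible"),
#'   `objective` (U), `flows` (data.frame commodity_id/from/to/flow),
#'   `commodities`, `cfg` and, when infeasible, a `diagnostic` suggesting a
#'   larger edge capacity.
#' @export
solve_flow <- function(g, commodities, cfg = capacity_config(),
                       solver = "highs") {
  stopifnot(inherits(g, "FlowGraph"), nrow(commodities) >= 1)
  n_arc <- nrow(g$arcs)
  K <- nrow(commodities)
  src <- match(commodities$source, g$nodes)
  snk <- match(commodities$sink, g$nodes)
  if (anyNA(src) || anyNA(snk)) stop("commodity endpoint not in graph")

  # variables: one per (commodity, admissible arc)
  arc_sets <- lapply(seq_len(K), function(i) {
    if (is.null(cfg$hop_limit)) seq_len(n_arc)
    else restrict_arcs(g, commodities$source[i], commodities$sink[i],
                       cfg$hop_limit)
  })
  if (any(lengths(arc_sets) == 0))
    stop("unreachable commodity in input; run drop_unreachable() first")
  var_comm <- rep(seq_len(K), lengths(arc_sets))
  var_arc <- unlist(arc_sets, use.names = FALSE)
  nv <- length(var_arc)

  # conservation: one row per (commodity, node incident to its arc set)
  rows_i <- integer(0); rows_j <- integer(0); rows_v <- numeric(0)
  b_eq <- numeric(0)
  row0 <- 0L
  node_rows <- vector("list", K)
  for (i in seq_len(K)) {
    vs <- which(var_comm == i)
    nd <- sort(unique(c(g$from_i[var_arc[vs]], g$to_i[var_arc[vs]],
                        src[i], snk[i])))
    rid <- match(seq_along(g$nodes), nd)     # node index -> local row
    rows_i <- c(rows_i,
                row0 + rid[g$from_i[var_arc[vs]]],
                row0 + rid[g$to_i[var_arc[vs]]])
    rows_j <- c(rows_j, vs, vs)
    rows_v <- c(rows_v, rep(1, length(vs)), rep(-1, length(vs)))
    b <- numeric(length(nd))
    b[match(src[i], nd)] <- commodities$demand[i]
    b[match(snk[i], nd)] <- -commodities$demand[i]
    b_eq <- c(b_eq, b)
    row0 <- row0 + length(nd)
  }
  A_eq <- list(i = rows_i, j = rows_j, v = rows_v)

  # capacities
  ui <- integer(0); uj <- integer(0); uv <- numeric(0); b_ub <- numeric(0)
  urow <- 0L
  if (is.finite(cfg$edge_capacity)) {
    load <- table(var_arc)
    hot <- as.integer(names(load))[load > cfg$edge_capacity]
    if (length(hot)) {
      sel <- var_arc %in% hot
      r <- match(var_arc, hot)
      ui <- c(ui, r[sel]); uj <- c(uj, which(sel)); uv <- c(uv, rep(1, sum(sel)))
      b_ub <- c(b_ub, rep(cfg$edge_capacity, length(hot)))
      urow <- length(hot)
    }
  }
  if (is.finite(cfg$node_capacity)) {
    into <- g$to_i[var_arc]
    load <- table(into)
    hot <- as.integer(names(load))[load > cfg$node_capacity]
    if (length(hot)) {
      sel <- into %in% hot
      r <- match(into, hot)
      ui <- c(ui, urow + r[sel]); uj <- c(uj, which(sel))
      uv <- c(uv, rep(1, sum(sel)))
      b_ub <- c(b_ub, rep(cfg$node_capacity, length(hot)))
    }
  }
  A_ub <- if (length(ui)) list(i = ui, j = uj, v = uv) else NULL

  res <- lp_solve(c = g$arcs$cost[var_arc], A_eq = A_eq, b_eq = b_eq,
                  A_ub = A_ub, b_ub = if (length(b_ub)) b_ub else NULL,
                  lb = 0, ub = 1, solver = solver)
  if (res$status == "infeasible") {
    return(structure(list(
      status = "infeasible", objective = NA_real_, flows = NULL,
      commodities = commodities, cfg = cfg,
      diagnostic = sprintf(
        "LP infeasible at edge capacity C = %g: shared arcs cannot carry all %d commodities. Retry with a larger C (e.g. %g) or a larger hop limit.",
        cfg$edge_capacity, K, cfg$edge_capacity + 1)),
      class = "FlowSolution"))
  }
  x <- res$x
  keep <- x > 1e-9
  flows <- data.frame(
    commodity_id = commodities$id[var_comm[keep]],
    from = g$arcs$from[var_arc[keep]],
    to = g$arcs$to[var_arc[keep]],
    flow = pmin(x[keep], 1),
    stringsAsFactors = FALSE)
  structure(list(status = "optimal", objective = res$objective, flows = flows,
                 commodities = commodities, cfg = cfg, diagnostic = NULL),
            class = "FlowSolution")
}

#' Verify feasibility residuals of a flow solution
#'
#' @param sol an optimal `FlowSolution`.
#' @param g the `FlowGraph` it was solved on.
#' @return list of maximal violations: `conservation`, `edge_capacity`,
#'   `node_capacity` (0 when the constraint is inactive).
#' @export
verify_flow_solution <- function(sol, g) {
  stopifnot(inherits(sol, "FlowSolution"), sol$status == "optimal")
  fl <- sol$flows
  comm <- sol$commodities
  cons <- 0
  for (i in seq_len(nrow(comm))) {
    f <- fl[fl$commodity_id == comm$id[i], , drop = FALSE]
    net <- rep(0, length(g$nodes)); names(net) <- g$nodes
    out <- tapply(f$flow, f$from, sum)
    inn <- tapply(f$flow, f$to, sum)
    net[names(out)] <- net[names(out)] + out
    net[names(inn)] <- net[names(inn)] - inn
    want <- rep(0, length(g$nodes)); names(want) <- g$nodes
    want[comm$source[i]] <- comm$demand[i]
    want[comm$sink[i]] <- -comm$demand[i]
    cons <- max(cons, max(abs(net - want)))
  }
  edge <- 0
  if (nrow(fl)) {
    tot <- tapply(fl$flow, paste(fl$from, fl$to), sum)
    edge <- max(0, max(tot) - sol$cfg$edge_capacity)
  }
  node <- 0
  if (is.finite(sol$cfg$node_capacity) && nrow(fl)) {
    tot <- tapply(fl$flow, fl$to, sum)
    node <- max(0, max(tot) - sol$cfg$node_capacity)
  }
  list(conservation = cons, edge_capacity = max(0, edge), node_capacity = node)
}

# lexicographically smallest simple s->t path in the arc subset `arcs`
# (data.frame from/to); NULL if none.
lex_path <- function(arcs, source, sink) {
  adj <- split(arcs$to, arcs$from)
  adj <- lapply(adj, sort)
  walk <- function(node, visited) {
    if (node == sink) return(list(node))
    for (nxt in setdiff(adj[[node]], visited)) {
      sub <- walk(nxt, c(visited, nxt))
      if (!is.null(sub)) return(c(list(node), sub))
    }
    NULL
  }
  p <- walk(source, source)
  if (is.null(p)) NULL else unlist(p)
}

# decompose one commodity's flow into weighted paths by repeatedly
# stripping the maximum-bottleneck s->t path (ties: lexicographic).
decompose_flow <- function(f, source, sink, tol = 1e-6) {
  paths <- list(); weights <- numeric(0)
  repeat {
    f <- f[f$flow > 1e-9, , drop = FALSE]
    out_s <- sum(f$flow[f$from == source])
    if (out_s <= 1e-9) break
    vals <- sort(unique(f$flow), decreasing = TRUE)
    best <- NULL
    for (v in vals) {
      cand <- lex_path(f[f$flow >= v - 1e-12, , drop = FALSE], source, sink)
      if (!is.null(cand)) { best <- cand; break }
    }
    if (is.null(best)) break
    key <- paste(best[-length(best)], best[-1])
    idx <- match(key, paste(f$from, f$to))
    w <- min(f$flow[idx])
    f$flow[idx] <- f$flow[idx] - w
    paths[[length(paths) + 1]] <- best
    weights <- c(weights, w)
  }
  residual <- sum(f$flow[f$from == source])
  if (residual > tol)
    stop(sprintf("flow decomposition left %.3g unaccounted at the source (solver tolerance problem?)", residual))
  list(paths = paths, weights = weights)
}

#' Extract one path per commodity from the LP solution
#'
#' Arcs carrying flow of at least `tau` are traversed from the source; when
#' they do not form a single source-sink path (fractional solutions), the
#' commodity's flow is decomposed into weighted paths by iteratively
#' stripping the maximum-bottleneck path, and the highest-weight path is
#' returned (ties broken by the lexicographically smaller node sequence).
#'
#' @param sol an optimal `FlowSolution`.
#' @param g the `FlowGraph`.
#' @param tau flow threshold for the integral fast path (default 0.5).
#' @return A `PatientPaths` data.frame: `commodity_id`, `patient_id`,
#'   `transition_rank`, `cost`, `weight`, and `nodes` (list column of node
#'   sequences source..sink).
#' @export
extract_paths <- function(sol, g, tau = 0.5) {
  stopifnot(inherits(sol, "FlowSolution"))
  if (sol$status != "optimal") stop("no paths: solution status is ", sol$status)
  comm <- sol$commodities
  cost_of <- function(nodes) {
    key <- paste(nodes[-length(nodes)], nodes[-1])
    idx <- match(key, paste(g$arcs$from, g$arcs$to))
    if (anyNA(idx)) stop("path uses an arc not present in the graph")
    sum(g$arcs$cost[idx])
  }
  out <- vector("list", nrow(comm))
  for (i in seq_len(nrow(comm))) {
    f <- sol$flows[sol$flows$commodity_id == comm$id[i], , drop = FALSE]
    s <- comm$source[i]; t <- comm$sink[i]
    path <- NULL; w <- 1
    thr <- f[f$flow >= tau, , drop = FALSE]
    if (nrow(thr) && !anyDuplicated(thr$from)) {
      # follow the unique thresholded out-arc from the source
      seqn <- s
      node <- s
      repeat {
        nxt <- thr$to[thr$from == node]
        if (length(nxt) != 1 || nxt %in% seqn) { seqn <- NULL; break }
        seqn <- c(seqn, nxt); node <- nxt
        if (node == t) break
      }
      if (!is.null(seqn) && length(seqn) == nrow(thr) + 1) path <- seqn
    }
    if (is.null(path)) {
      dec <- decompose_flow(f, s, t)
      if (!length(dec$paths)) stop("no source-sink path in flow of commodity ", comm$id[i])
      best <- max(dec$weights)
      cand <- dec$paths[dec$weights >= best - 1e-12]
      keys <- vapply(cand, paste, character(1), collapse = "\r")
      pick <- cand[[order(keys)[1]]]
      path <- pick
      w <- best
    }
    out[[i]] <- list(commodity_id = comm$id[i], patient_id = comm$patient_id[i],
                     transition_rank = comm$transition_rank[i],
                     cost = cost_of(path), weight = w, nodes = path)
  }
  res <- data.frame(
    commodity_id = vapply(out, `[[`, numeric(1), "commodity_id"),
    patient_id = vapply(out, `[[`, character(1), "patient_id"),
    transition_rank = vapply(out, `[[`, numeric(1), "transition_rank"),
    cost = vapply(out, `[[`, numeric(1), "cost"),
    weight = vapply(out, `[[`, numeric(1), "weight"),
    stringsAsFactors = FALSE)
  res$nodes <- lapply(out, `[[`, "nodes")
  class(res) <- c("PatientPaths", "data.frame")
  res
}

#' Export a flow solution as JSON
#' @param sol a `FlowSolution`.
#' @param path output file.
#' @export
write_flow_json <- function(sol, path) {
  jsonlite::write_json(
    list(status = sol$status, objective = sol$objective, flows = sol$flows),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export per-patient paths as TSV
#' @param paths a `PatientPaths` data.frame.
#' @param path output file.
#' @export
write_paths_tsv <- function(paths, path) {
  df <- data.frame(patient_id = paths$patient_id,
                   transition_rank = paths$transition_rank,
                   nodes = vapply(paths$nodes, paste, character(1), collapse = ","),
                   cost = paths$cost)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
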