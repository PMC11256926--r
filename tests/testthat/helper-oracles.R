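# Independent reference implementations used as test oracles. These are
# deliberately naive (loops, exhaustive enumeration) and share no code with
# the package internals they check.

# --- TMM: direct transcription of the published trimmed-mean-of-M-values
#     procedure (30% M trim, 5% A trim, precision weights, UQ reference).
oracle_tmm <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  one_factor <- function(obs, refc) {
    nO <- sum(obs); nR <- sum(refc)
    logR <- log2((obs / nO) / (refc / nR))
    absE <- (log2(obs / nO) + log2(refc / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    2^f
  }
  f <- vapply(seq_len(ncol(counts)),
              function(j) one_factor(counts[, j], counts[, ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# --- random directed flow instance built on an undirected GNM graph with
#     uniform costs; guarantees s-t reachability by construction.
random_flow_instance <- function(n, m, seed, n_comm = 1) {
  set.seed(seed)
  repeat {
    ig <- igraph::sample_gnm(n, m)
    if (igraph::is_connected(ig)) break
  }
  el <- igraph::as_edgelist(ig)
  ids <- sprintf("n%02d", seq_len(n))
  edges <- data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                      cost = round(stats::runif(nrow(el), 0.1, 2), 3),
                      stringsAsFactors = FALSE)
  g <- trajflow::flow_graph(edges, nodes = ids)
  ends <- replicate(n_comm, sample(ids, 2))
  comm <- data.frame(id = seq_len(n_comm), source = ends[1, ], sink = ends[2, ],
                     demand = 1,
                     patient_id = sprintf("p%d", seq_len(n_comm)),
                     transition_rank = 1L, stringsAsFactors = FALSE)
  class(comm) <- c("CommoditySet", "data.frame")
  list(graph = g, commodities = comm, igraph = ig, ids = ids, edges = edges)
}

dijkstra_cost <- function(inst, source, sink) {
  ig <- igraph::graph_from_data_frame(
    rbind(inst$edges, data.frame(from = inst$edges$to, to = inst$edges$from,
                                 cost = inst$edges$cost)),
    directed = TRUE, vertices = data.frame(name = inst$ids))
  igraph::distances(ig, v = source, to = sink, mode = "out",
                    weights = igraph::E(ig)$cost)[1, 1]
}

# --- all arcs lying on some s->t walk of at most l hops, by exhaustive DFS
#     over walks (node repeats allowed).
enumerate_walk_arcs <- function(g, source, sink, l) {
  arcs_key <- paste(g$arcs$from, g$arcs$to)
  found <- character(0)
  recurse <- function(node, walk_arcs, depth) {
    if (node == sink && length(walk_arcs))
      found <<- unique(c(found, walk_arcs))
    if (depth == l) return()
    out <- which(g$arcs$from == node)
    for (a in out) recurse(g$arcs$to[a], c(walk_arcs, arcs_key[a]), depth + 1)
  }
  recurse(source, character(0), 0)
  sort(match(found, arcs_key))
}

# --- exhaustive integral multi-commodity routing: every combination of
#     simple paths, feasibility checked against edge capacity.
brute_force_mcf <- function(inst, C, max_hops = -1) {
  ig <- igraph::graph_from_data_frame(
    rbind(inst$edges, data.frame(from = inst$edges$to, to = inst$edges$from,
                                 cost = inst$edges$cost)),
    directed = TRUE, vertices = data.frame(name = inst$ids))
  cost_lookup <- stats::setNames(
    c(inst$edges$cost, inst$edges$cost),
    c(paste(inst$edges$from, inst$edges$to),
      paste(inst$edges$to, inst$edges$from)))
  path_sets <- lapply(seq_len(nrow(inst$commodities)), function(i) {
    ps <- igraph::all_simple_paths(ig, from = inst$commodities$source[i],
                                   to = inst$commodities$sink[i],
                                   cutoff = max_hops)
    lapply(ps, function(p) igraph::as_ids(p))
  })
  if (any(lengths(path_sets) == 0)) return(list(feasible = FALSE, cost = Inf))
  best <- Inf; feasible <- FALSE
  combo <- function(i, loads, total) {
    if (total >= best) return()
    if (i > length(path_sets)) { best <<- total; feasible <<- TRUE; return() }
    for (p in path_sets[[i]]) {
      keys <- paste(p[-length(p)], p[-1])
      new_loads <- loads
      for (k in keys) new_loads[k] <- ifelse(is.na(new_loads[k]), 1, new_loads[k] + 1)
      if (any(new_loads > C, na.rm = TRUE)) next
      combo(i + 1, new_loads, total + sum(cost_lookup[keys]))
    }
  }
  combo(1, stats::setNames(numeric(0), character(0)), 0)
  list(feasible = feasible, cost = best)
}

# --- exact two-sample KS p-values from scipy, as an independent reference.
scipy_ks_pvalues <- function(amat, bmat) {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(list(a = unname(amat), b = unname(bmat)), fin,
                       digits = NA, matrix = "rowmajor")
  py <- Sys.which("python"); if (!nzchar(py)) py <- Sys.which("python3")
  code <- paste(
    "import json, sys",
    "from scipy.stats import ks_2samp",
    "d = json.load(open(sys.argv[1]))",
    "p = [float(ks_2samp(ra, rb, method='exact').pvalue) for ra, rb in zip(d['a'], d['b'])]",
    "json.dump(p, open(sys.argv[2], 'w'))",
    sep = "; ")
  st <- system2(py, c("-c", shQuote(code), shQuote(fin), shQuote(fout)),
                stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(st, "status"))) stop("scipy oracle failed: ", paste(st, collapse = "\n"))
  unlist(jsonlite::read_json(fout, simplifyVector = TRUE))
}

# small labeled count matrix helper
toy_matrix <- function(values, kind = "counts", genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  trajflow::expression_matrix(values, kind)
}
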