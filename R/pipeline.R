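#' Pipeline run configuration
#'
#' All tunable parameters of the end-to-end pipeline, with validation:
#' unknown keys are rejected, and every run writes the resolved config
#' (plus tool version and config hash) next to its outputs.
#'
#' @param ... parameter overrides; see Details for names and defaults.
#' @details Parameters: `cpm_threshold` (0.25), `min_fraction` (0.01),
#'   `log_transform` (TRUE), `n_pcs` (10), `n_neighbors` (15),
#'   `resolution` (NULL = silhouette-based auto-selection, see
#'   [select_resolution()]), `edge_capacity` (1), `node_capacity` (Inf),
#'   `hop_limit` (NULL), `escalate_capacity` (FALSE; when the LP is
#'   infeasible retry with the capacity doubled, up to `max_edge_capacity`
#'   (64) — always logged, never silent), `flow_threshold` (0.5),
#'   `trajectory_length` (4), `top_k` (5),
#'   `prune_mass` (NULL = no pruning), `solver` ("highs"), `seed` (1).
#' @return A `RunConfig` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    cpm_threshold = 0.25, min_fraction = 0.01, log_transform = TRUE,
    n_pcs = 10L, n_neighbors = 15L, resolution = NULL,
    edge_capacity = 1, node_capacity = Inf, hop_limit = NULL,
    escalate_capacity = FALSE, max_edge_capacity = 64,
    flow_threshold = 0.5, trajectory_length = 4L, top_k = 5L,
    prune_mass = NULL, solver = "highs", seed = 1L)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, class = "RunConfig")
}

#' @rdname run_config
#' @param path YAML file of overrides.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

# deterministic per-stage seed derived from the master seed (kept < 2^31)
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(master) * 48271 + h * 16807) %% 2147483647
}

log_stage <- function(fmt, ...) {
  message(sprintf("[trajflow] %s", sprintf(fmt, ...)))
}

#' Run the full trajectory-inference pipeline
#'
#' load/normalize -> PCA -> fuzzy kNN graph -> Leiden states -> commodities
#' -> corridor restriction and unreachable-commodity removal -> flow LP ->
#' per-patient paths -> state diagram -> ranked trajectories. Every
#' intermediate artifact is written under `out_dir`. An infeasible LP is a
#' distinct error (`trajflow_infeasible` condition) carrying the suggestion
#' to raise the edge capacity, unless `escalate_capacity` is on.
#'
#' @param m an `ExpressionMatrix` (counts or normalized).
#' @param meta a `SampleMeta` for the matrix.
#' @param config a [run_config()].
#' @param out_dir artifact directory (created).
#' @return Invisibly, a list with all intermediate objects: `matrix`,
#'   `factors`, `embedding`, `graph`, `states`, `commodities`, `dropped`,
#'   `solution`, `paths`, `diagram`, `trajectories`, `config`.
#' @export
run_pipeline <- function(m, meta, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- proc.time()[3]
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_to <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)

  log_stage("preprocess: %d genes x %d samples (%s)",
            nrow(m$values), ncol(m$values), m$data_kind)
  pp <- preprocess_counts(m, cpm_threshold = config$cpm_threshold,
                          min_fraction = config$min_fraction)
  norm <- pp$matrix
  log_stage("preprocess: %d genes retained", nrow(norm$values))
  if (!is.null(out_dir)) {
    write_expression_delim(norm, save_to("normalized.tsv"))
    if (!is.null(pp$factors)) write_tmm_factors(pp$factors, save_to("tmm_factors.tsv"))
  }

  emb <- pca_embed(norm, d = min(config$n_pcs, ncol(norm$values) - 1L),
                   log_transform = config$log_transform && m$data_kind == "counts")
  log_stage("embedding: %d PCs", emb$d)
  cg <- fuzzy_graph(emb, n_neighbors = config$n_neighbors)
  log_stage("graph: %d nodes, %d fuzzy edges", length(cg$nodes), nrow(cg$edges))
  states <- if (is.null(config$resolution)) {
    select_resolution(cg, emb, seed = stage_seed(config$seed, "states"))
  } else {
    leiden_states(cg, resolution = config$resolution,
                  seed = stage_seed(config$seed, "states"))
  }
  log_stage("states: %d Leiden clusters (resolution %.2f)",
            states$n_states, states$resolution)
  if (!is.null(out_dir)) {
    write_graphml(cg, save_to("graph.graphml"))
    write_edges_tsv(cg, save_to("graph_edges.tsv"))
    write_states_tsv(states, save_to("states.tsv"))
  }

  g <- flow_graph_from_embedding(cg, emb)
  comm <- build_commodities(meta[meta$sample_id %in% g$nodes, , drop = FALSE])
  log_stage("commodities: %d from %d patients", nrow(comm),
            length(unique(comm$patient_id)))
  dr <- drop_unreachable(comm, g, config$hop_limit)
  if (nrow(dr$dropped))
    log_stage("commodities: dropped %d/%d unreachable (%.1f%%)",
              nrow(dr$dropped), nrow(comm), 100 * nrow(dr$dropped) / nrow(comm))
  if (!nrow(dr$kept)) stop("no reachable commodities")
  if (!is.null(out_dir))
    utils::write.table(as.data.frame(dr$kept), save_to("commodities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  C <- config$edge_capacity
  repeat {
    cfg <- capacity_config(edge_capacity = C,
                           node_capacity = config$node_capacity,
                           hop_limit = config$hop_limit)
    sol <- solve_flow(g, dr$kept, cfg, solver = config$solver)
    if (sol$status == "optimal") break
    if (!config$escalate_capacity || C * 2 > config$max_edge_capacity) {
      cond <- structure(class = c("trajflow_infeasible", "error", "condition"),
                        list(message = sol$diagnostic, call = sys.call()))
      stop(cond)
    }
    log_stage("flow: infeasible at C = %g, escalating to C = %g", C, C * 2)
    C <- C * 2
  }
  log_stage("flow: optimal, U = %.4f (C = %g)", sol$objective, C)
  paths <- extract_paths(sol, g, tau = config$flow_threshold)
  if (!is.null(out_dir)) {
    write_flow_json(sol, save_to("flow.json"))
    write_paths_tsv(paths, save_to("paths.tsv"))
  }

  diagram <- build_diagram(paths, states)
  if (!is.null(config$prune_mass)) diagram <- prune_diagram(diagram, config$prune_mass)
  traj <- top_trajectories(diagram, length = config$trajectory_length,
                           k = config$top_k)
  log_stage("trajectories: top %s (score %.3g)", traj$states[1], traj$score[1])
  if (!is.null(out_dir)) {
    write_diagram_json(diagram, save_to("diagram.json"))
    write_diagram_dot(diagram, save_to("diagram.dot"))
    write_trajectories_tsv(traj, save_to("trajectories.tsv"))
    resolved <- unclass(config)
    resolved$edge_capacity_used <- C
    resolved$version <- as.character(utils::packageVersion("trajflow"))
    cfg_path <- save_to("config_resolved.yaml")
    yaml::write_yaml(lapply(resolved, function(v) if (is.null(v)) NA else v), cfg_path)
    resolved$config_hash <- unname(tools::md5sum(cfg_path))
    yaml::write_yaml(lapply(resolved, function(v) if (is.null(v)) NA else v), cfg_path)
  }
  log_stage("done in %.1f s", proc.time()[3] - t0)
  invisible(list(matrix = norm, factors = pp$factors, embedding = emb,
                 graph = cg, states = states, commodities = comm,
                 dropped = dr$dropped, solution = sol, paths = paths,
                 diagram = diagram, trajectories = traj, config = config,
                 edge_capacity_used = C))
}
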