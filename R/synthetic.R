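#' Specification of a synthetic short-time-series cohort
#'
#' Describes a cohort of patients whose latent disease course follows one of
#' a few planted state sequences (endotypes). Patients observe only a subset
#' of their trajectory positions — the core regime for flow-based trajectory
#' inference, which must route the resulting transitions through other
#' patients' samples. Latent positions are the planted state centers plus
#' isotropic Gaussian noise; expression is a fixed random linear map of the
#' latent space through a softplus, scaled to count-like magnitudes with
#' mild library-size variation.
#'
#' The default geometry is a Y: a shared trunk of states 0-1-2 branching
#' into arms 3-4 and 5-6, consecutive centers `center_spacing` apart in a
#' 2-D latent space, and two equally weighted endotypes 0-1-2-3-4 and
#' 0-1-2-5-6. With the default `noise_sd = 1` and `center_spacing = 6` the
#' states are well separated (6 sd).
#'
#' @param n_patients number of patients (default 60).
#' @param visits_per_patient observed visits per patient (default 3);
#'   positions are a uniform random subset of the trajectory
#'   (`observed_rule = "random"`, default, which keeps state occupancy
#'   balanced), or always include the first and last position with uniform
#'   interior picks (`"endpoints"`), or all positions (`"all"`).
#' @param endotypes list of planted state sequences (0-based, no
#'   consecutive repeats).
#' @param endotype_weights sampling weights, summing to 1.
#' @param state_centers n_states x d_latent matrix of latent centers; the
#'   default builds the Y geometry for 7 states.
#' @param center_spacing distance between consecutive centers in the
#'   default geometry (ignored when `state_centers` is given).
#' @param noise_sd isotropic latent noise sd (default 1).
#' @param n_genes genes in the emitted matrix (default 500).
#' @param loading_sd sd of the random latent->gene loading entries.
#' @param baseline_range uniform range of per-gene baseline offsets.
#' @param count_scale multiplier taking softplus activations to count-like
#'   magnitudes (default 10).
#' @param depth_sd sd of log-normal per-sample library-depth factors.
#' @param dropout_visit_prob probability each observed visit is dropped;
#'   patients left with < 2 visits are regenerated.
#' @param observed_rule visit-position rule, see `visits_per_patient`.
#' @param seed RNG seed.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(n_patients = 60L, visits_per_patient = 3L,
                        endotypes = list(c(0L, 1L, 2L, 3L, 4L),
                                         c(0L, 1L, 2L, 5L, 6L)),
                        endotype_weights = NULL, state_centers = NULL,
                        center_spacing = 6, noise_sd = 1, n_genes = 500L,
                        loading_sd = NULL, baseline_range = c(1, 3),
                        count_scale = 10, depth_sd = 0.2,
                        dropout_visit_prob = 0,
                        observed_rule = c("random", "endpoints", "all"),
                        seed = 1L) {
  observed_rule <- match.arg(observed_rule)
  if (is.null(endotype_weights))
    endotype_weights <- rep(1 / length(endotypes), length(endotypes))
  stopifnot(length(endotype_weights) == length(endotypes),
            abs(sum(endotype_weights) - 1) < 1e-8,
            noise_sd >= 0, dropout_visit_prob >= 0, dropout_visit_prob < 1,
            visits_per_patient >= 2)
  for (e in endotypes)
    if (any(diff(e) == 0)) stop("endotype sequences must have no consecutive repeats")
  n_states <- max(unlist(endotypes)) + 1L
  if (is.null(state_centers)) {
    u <- center_spacing
    a <- pi / 4
    state_centers <- rbind(
      c(0, 0), c(u, 0), c(2 * u, 0),
      c(2 * u + u * cos(a), u * sin(a)), c(2 * u + 2 * u * cos(a), 2 * u * sin(a)),
      c(2 * u + u * cos(a), -u * sin(a)), c(2 * u + 2 * u * cos(a), -2 * u * sin(a)))
    state_centers <- state_centers[seq_len(max(n_states, 2)), , drop = FALSE]
    # center at the origin: state differences are then compositional shifts
    # rather than overall-abundance changes, which library-size (CPM)
    # normalization would otherwise flatten
    state_centers <- sweep(state_centers, 2, colMeans(state_centers))
  }
  if (nrow(state_centers) < n_states)
    stop("state_centers has fewer rows than states referenced by endotypes")
  d_latent <- ncol(state_centers)
  if (is.null(loading_sd)) loading_sd <- 1 / sqrt(d_latent)
  structure(list(
    n_states = nrow(state_centers), state_centers = state_centers,
    endotypes = endotypes, endotype_weights = endotype_weights,
    n_patients = as.integer(n_patients),
    visits_per_patient = as.integer(visits_per_patient),
    observed_rule = observed_rule, noise_sd = noise_sd,
    n_genes = as.integer(n_genes), loading_sd = loading_sd,
    baseline_range = baseline_range, count_scale = count_scale,
    depth_sd = depth_sd, dropout_visit_prob = dropout_visit_prob,
    seed = as.integer(seed)),
    class = "CohortSpec")
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Simulate a synthetic cohort with planted trajectories
#'
#' @param spec a [cohort_spec()].
#' @return list with `matrix` (counts `ExpressionMatrix`), `meta`
#'   (`SampleMeta`; `visit_rank` = trajectory position, so skipped positions
#'   appear as missing visits) and `truth` (`GroundTruth`: per-patient
#'   endotype index, per-sample planted state and latent coordinates, the
#'   planted `StateDiagram`, and the spec).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  d_latent <- ncol(spec$state_centers)
  loading <- matrix(stats::rnorm(d_latent * spec$n_genes, sd = spec$loading_sd),
                    d_latent, spec$n_genes)
  baseline <- stats::runif(spec$n_genes, spec$baseline_range[1], spec$baseline_range[2])

  meta <- list(); latent <- list(); planted_state <- integer(0)
  built_ids <- character(0)
  endo_of <- integer(spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", p)
    endo <- sample.int(length(spec$endotypes), 1, prob = spec$endotype_weights)
    endo_of[p] <- endo
    traj <- spec$endotypes[[endo]]
    L <- length(traj)
    for (try in seq_len(100)) {
      pos <- switch(spec$observed_rule,
        all = seq_len(L),
        endpoints = {
          if (spec$visits_per_patient >= L) seq_len(L)
          else sort(c(1, L, sample(2:(L - 1), spec$visits_per_patient - 2)))
        },
        random = sort(sample.int(L, min(spec$visits_per_patient, L))))
      if (spec$dropout_visit_prob > 0)
        pos <- pos[stats::runif(length(pos)) >= spec$dropout_visit_prob]
      if (length(pos) >= 2) break
      if (try == 100) stop("could not draw >= 2 observed visits for ", pid)
    }
    for (v in pos) {
      st <- traj[v]
      z <- spec$state_centers[st + 1, ] +
        stats::rnorm(d_latent, sd = spec$noise_sd)
      sid <- sprintf("%s_V%d", pid, v - 1)
      meta[[length(meta) + 1]] <- data.frame(
        sample_id = sid, patient_id = pid, visit_rank = v - 1L,
        visit_label = paste0("V", v - 1L), stringsAsFactors = FALSE)
      latent[[length(latent) + 1]] <- z
      planted_state <- c(planted_state, st)
      built_ids <- c(built_ids, sid)
    }
  }
  meta <- sample_meta(do.call(rbind, meta))
  Z <- do.call(rbind, latent)

  depth <- exp(stats::rnorm(nrow(Z), 0, spec$depth_sd))
  act <- softplus(sweep(Z %*% loading, 2, baseline, "+"))
  counts <- round(spec$count_scale * act * depth)
  values <- t(counts)
  rownames(values) <- sprintf("G%04d", seq_len(spec$n_genes))
  colnames(values) <- built_ids
  values <- values[, meta$sample_id, drop = FALSE]
  m <- expression_matrix(values, "counts")

  # planted diagram from the realized endotype draws
  K <- spec$n_states
  counts_mat <- matrix(0L, K, K, dimnames = list(0:(K - 1), 0:(K - 1)))
  first <- integer(0); last <- integer(0)
  for (p in seq_len(spec$n_patients)) {
    traj <- spec$endotypes[[endo_of[p]]]
    for (j in seq_len(length(traj) - 1))
      counts_mat[traj[j] + 1, traj[j + 1] + 1] <-
        counts_mat[traj[j] + 1, traj[j + 1] + 1] + 1L
    first <- c(first, traj[1]); last <- c(last, traj[length(traj)])
  }
  planted <- new_state_diagram(counts_mat,
                               tabulate(first + 1L, K) / length(first),
                               tabulate(last + 1L, K) / length(last))
  truth <- structure(list(
    patient_endotype = stats::setNames(endo_of, sprintf("P%03d", seq_len(spec$n_patients))),
    endotype_sequences = spec$endotypes,
    sample_state = stats::setNames(planted_state, built_ids),
    latent = {rownames(Z) <- built_ids; Z},
    planted_diagram = planted, spec = spec), class = "GroundTruth")
  list(matrix = m, meta = meta, truth = truth)
}

#' Planted-trajectory recovery score
#'
#' Fraction of planted endotype state sequences that appear exactly among
#' the top-k inferred trajectories, under the best label mapping: inferred
#' cluster labels are arbitrary, so an injective inferred-state ->
#' planted-state map is chosen (by backtracking unification across all
#' matched pairs) to maximize the number of recovered sequences.
#'
#' @param inferred a `TrajectoryList` from [top_trajectories()], or a list
#'   of 0-based integer state vectors.
#' @param truth a `GroundTruth` from [simulate_cohort()].
#' @param k number of top inferred trajectories considered (default: number
#'   of planted endotypes).
#' @return Recovery score in `[0, 1]`.
#' @export
recovery_score <- function(inferred, truth,
                           k = length(truth$endotype_sequences)) {
  stopifnot(inherits(truth, "GroundTruth"))
  if (inherits(inferred, "TrajectoryList") ||
      (is.data.frame(inferred) && "states" %in% names(inferred))) {
    inferred <- lapply(strsplit(inferred$states, "-", fixed = TRUE), as.integer)
  }
  inferred <- inferred[seq_len(min(k, length(inferred)))]
  planted <- truth$endotype_sequences
  # unify(map) pairing planted sequences with inferred ones; map is
  # inferred-label -> planted-label, injective
  try_pair <- function(pl, inf, map) {
    if (length(pl) != length(inf)) return(NULL)
    for (j in seq_along(pl)) {
      key <- as.character(inf[j])
      if (!is.null(map[[key]])) {
        if (map[[key]] != pl[j]) return(NULL)
      } else {
        if (pl[j] %in% unlist(map)) return(NULL)  # injectivity
        map[[key]] <- pl[j]
      }
    }
    map
  }
  best <- 0
  rec <- function(i, map, used, matched) {
    if (matched + (length(planted) - i + 1) <= best) return()
    if (i > length(planted)) { best <<- max(best, matched); return() }
    for (j in seq_along(inferred)) {
      if (used[j]) next
      m2 <- try_pair(planted[[i]], inferred[[j]], map)
      if (!is.null(m2)) {
        used[j] <- TRUE
        rec(i + 1, m2, used, matched + 1)
        used[j] <- FALSE
      }
    }
    rec(i + 1, map, used, matched)   # leave this planted sequence unmatched
  }
  rec(1, list(), logical(length(inferred)), 0)
  best / length(planted)
}

#' Write a ground-truth object as JSON
#' @param truth a `GroundTruth`.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    patient_endotype = as.list(truth$patient_endotype),
    endotype_sequences = truth$endotype_sequences,
    sample_state = as.list(truth$sample_state)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read/write a cohort spec as YAML
#' @param spec a `CohortSpec`.
#' @param path file path.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  x$state_centers <- apply(spec$state_centers, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$state_centers <- do.call(rbind, x$state_centers)
  x$endotypes <- lapply(x$endotypes, as.integer)
  do.call(cohort_spec, x[intersect(names(x), names(formals(cohort_spec)))])
}
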