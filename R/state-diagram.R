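#' Aggregate patient paths into a state-transition diagram
#'
#' Each per-patient path is mapped from samples to disease states,
#' consecutive repeats are collapsed (so a path visiting states 0-0-5
#' contributes a single 0->5 transition and no self-loops), and all
#' consecutive state pairs are tallied into a transition-count matrix.
#' Initial-state probabilities are estimated from the state of each
#' patient's first observed visit, final-state probabilities from each
#' patient's last observed visit.
#'
#' @param paths a `PatientPaths` data.frame from [extract_paths()].
#' @param states a `StateAssignment` covering every path node.
#' @return A `StateDiagram`: list with `n_states`, `transition_counts`,
#'   `transition_probs` (row-stochastic; all-zero rows are flagged in
#'   `absorbing` and excluded from walks), `init_probs`, `final_probs`.
#' @export
build_diagram <- function(paths, states) {
  stopifnot(inherits(states, "StateAssignment"))
  if (!nrow(paths)) stop("empty path list")
  K <- states$n_states
  lab <- states$labels
  state_seq <- lapply(paths$nodes, function(nd) {
    s <- lab[nd]
    if (anyNA(s)) stop("path node without a state label")
    unname(s[c(TRUE, diff(s) != 0)])  # collapse consecutive repeats
  })
  counts <- matrix(0L, K, K, dimnames = list(0:(K - 1), 0:(K - 1)))
  for (s in state_seq) {
    if (length(s) < 2) next
    for (j in seq_len(length(s) - 1))
      counts[s[j] + 1, s[j + 1] + 1] <- counts[s[j] + 1, s[j + 1] + 1] + 1L
  }
  # endpoint probabilities from each patient's first/last observed visit
  first_state <- integer(0); last_state <- integer(0)
  for (p in unique(paths$patient_id)) {
    rows <- which(paths$patient_id == p)
    r_first <- rows[which.min(paths$transition_rank[rows])]
    r_last <- rows[which.max(paths$transition_rank[rows])]
    first_state <- c(first_state, state_seq[[r_first]][1])
    sl <- state_seq[[r_last]]
    last_state <- c(last_state, sl[length(sl)])
  }
  init <- tabulate(first_state + 1L, K) / length(first_state)
  final <- tabulate(last_state + 1L, K) / length(last_state)
  new_state_diagram(counts, init, final)
}

new_state_diagram <- function(counts, init, final) {
  K <- nrow(counts)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(n_states = K, transition_counts = counts,
                 transition_probs = probs, absorbing = rs == 0,
                 init_probs = init, final_probs = final),
            class = "StateDiagram")
}

#' @export
print.StateDiagram <- function(x, ...) {
  cat(sprintf("StateDiagram: %d states, %d transitions observed\n",
              x$n_states, sum(x$transition_counts)))
  invisible(x)
}

#' Rank the most likely state trajectories
#'
#' Scores every state sequence with `length` transitions and no consecutive
#' repeats as `init_probs[s0] * prod(transition_probs[s_k, s_k+1]) *
#' final_probs[sL]`, by exact enumeration (state spaces here are small, so
#' enumeration is preferred over sampled random walks and is deterministic).
#' Sequences are ranked by score, descending; ties broken lexicographically.
#'
#' @param d a `StateDiagram`.
#' @param length number of transitions per trajectory (>= 1).
#' @param k number of trajectories to return.
#' @return A `TrajectoryList` data.frame: `rank`, `states` ("0-5-2"-style
#'   string), `score`, `length`, and `subsequence_of` — the rank of the
#'   closest higher-ranked trajectory that contains this one as an ordered
#'   subsequence (NA otherwise; reported as an annotation, not a filter).
#' @export
top_trajectories <- function(d, length, k = 5) {
  stopifnot(inherits(d, "StateDiagram"), length >= 1, k >= 1)
  K <- d$n_states
  if (K^length > 1e7)
    stop("state-sequence space too large for exact enumeration; reduce `length` or sample walks instead")
  P <- d$transition_probs
  seqs <- list(); scores <- numeric(0)
  walk <- function(prefix, score) {
    if (base::length(prefix) == length + 1) {
      seqs[[base::length(seqs) + 1]] <<- prefix
      scores[base::length(scores) + 1] <<- score * d$final_probs[prefix[base::length(prefix)] + 1]
      return()
    }
    cur <- prefix[base::length(prefix)]
    for (nxt in setdiff(0:(K - 1), cur))
      walk(c(prefix, nxt), score * P[cur + 1, nxt + 1])
  }
  for (s0 in 0:(K - 1)) walk(s0, d$init_probs[s0 + 1])
  key <- vapply(seqs, paste, character(1), collapse = "-")
  ord <- order(-scores, key)
  top <- ord[seq_len(min(k, base::length(ord)))]
  res <- data.frame(rank = seq_along(top), states = key[top],
                    score = scores[top], length = length,
                    stringsAsFactors = FALSE)
  # annotate ordered-subsequence redundancy against higher-ranked entries
  is_subseq <- function(a, b) {  # a subsequence of b?
    j <- 1
    for (x in b) if (j <= base::length(a) && a[j] == x) j <- j + 1
    j > base::length(a)
  }
  seq_top <- lapply(seqs[top], identity)
  res$subsequence_of <- vapply(seq_along(top), function(i) {
    if (i == 1) return(NA_integer_)
    hit <- which(vapply(seq_len(i - 1), function(j)
      is_subseq(seq_top[[i]], seq_top[[j]]), logical(1)))
    if (base::length(hit)) hit[1] else NA_integer_
  }, integer(1))
  class(res) <- c("TrajectoryList", "data.frame")
  res
}

#' Prune a diagram to its dominant transitions
#'
#' Per state, outgoing transitions are sorted by weight (raw transition
#' counts) descending and the shortest prefix whose cumulative weight
#' reaches `mass` of the state's total outgoing weight is kept; the rest
#' are zeroed and probabilities renormalized over the kept transitions.
#' The kept set is always recomputed from the raw counts (which the pruned
#' object retains), so pruning at a fixed mass is idempotent.
#'
#' @param d a `StateDiagram`.
#' @param mass fraction of outgoing weight to retain, in (0, 1].
#' @return A pruned `StateDiagram`.
#' @export
prune_diagram <- function(d, mass = 0.5) {
  stopifnot(inherits(d, "StateDiagram"), mass > 0, mass <= 1)
  K <- d$n_states
  probs <- matrix(0, K, K, dimnames = dimnames(d$transition_counts))
  for (s in seq_len(K)) {
    w <- d$transition_counts[s, ]
    tot <- sum(w)
    if (tot == 0) next
    ord <- order(-w, seq_len(K))   # ties: lexicographic by target state
    ord <- ord[w[ord] > 0]
    cum <- cumsum(w[ord])
    keep <- ord[seq_len(which(cum >= mass * tot)[1])]
    probs[s, keep] <- w[keep] / sum(w[keep])
  }
  out <- d
  out$transition_probs <- probs
  out$pruned_mass <- mass
  out
}

#' Export a state diagram as JSON or Graphviz DOT
#' @param d a `StateDiagram`.
#' @param path output file.
#' @export
write_diagram_json <- function(d, path) {
  jsonlite::write_json(
    list(n_states = d$n_states,
         transition_counts = d$transition_counts,
         transition_probs = d$transition_probs,
         init_probs = d$init_probs, final_probs = d$final_probs),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_diagram_json
#' @export
write_diagram_dot <- function(d, path) {
  lines <- c("digraph states {")
  idx <- which(d$transition_probs > 0, arr.ind = TRUE)
  lines <- c(lines, sprintf('  %d -> %d [label="%.3f"];',
                            idx[, 1] - 1, idx[, 2] - 1,
                            d$transition_probs[idx]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export ranked trajectories as TSV
#' @param tr a `TrajectoryList`.
#' @param path output file.
#' @export
write_trajectories_tsv <- function(tr, path) {
  utils::write.table(as.data.frame(tr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
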