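# Build a PatientPaths object directly (what extract_paths returns).
make_paths <- function(node_lists, patients = NULL, ranks = NULL) {
  n <- length(node_lists)
  if (is.null(patients)) patients <- sprintf("p%d", seq_len(n))
  if (is.null(ranks)) ranks <- rep(1L, n)
  if (n == 0) patients <- character(0)
  df <- data.frame(commodity_id = seq_len(n), patient_id = patients,
                   transition_rank = ranks, cost = rep(0, n),
                   weight = rep(1, n), stringsAsFactors = FALSE)
  df$nodes <- node_lists
  class(df) <- c("PatientPaths", "data.frame")
  df
}

make_states <- function(labels) {
  structure(list(labels = labels, n_states = max(labels) + 1L, resolution = 1),
            class = "StateAssignment")
}

test_that("a path through states 0-5-2-7 counts those three transitions", {
  ids <- c("a", "b", "c", "d")
  states <- make_states(setNames(c(0L, 5L, 2L, 7L), ids))
  d <- build_diagram(make_paths(list(ids)), states)
  expect_equal(d$transition_counts["0", "5"], 1L)
  expect_equal(d$transition_counts["5", "2"], 1L)
  expect_equal(d$transition_counts["2", "7"], 1L)
  expect_equal(sum(d$transition_counts), 3L)
  expect_equal(sum(diag(d$transition_counts)), 0L)
  expect_equal(d$init_probs[1], 1)   # state 0
  expect_equal(d$final_probs[8], 1)  # state 7
})

test_that("consecutive repeated states collapse to a single transition", {
  ids <- c("a", "b", "c")
  states <- make_states(setNames(c(0L, 0L, 5L), ids))
  d <- build_diagram(make_paths(list(ids)), states)
  expect_equal(d$transition_counts["0", "5"], 1L)
  expect_equal(sum(d$transition_counts), 1L)
  expect_equal(sum(diag(d$transition_counts)), 0L)
  expect_error(build_diagram(make_paths(list()), states), "empty")
})

test_that("transition counts match a naive tally over 100 random paths", {
  set.seed(17)
  n_nodes <- 40
  ids <- sprintf("s%02d", 1:n_nodes)
  lab <- setNames(sample(0L:4L, n_nodes, replace = TRUE), ids)
  paths <- lapply(1:100, function(i) sample(ids, sample(2:6, 1)))
  d <- build_diagram(make_paths(paths), make_states(lab))
  want <- matrix(0L, 5, 5)
  for (p in paths) {
    s <- unname(lab[p])
    s <- s[c(TRUE, diff(s) != 0)]
    if (length(s) < 2) next
    for (j in seq_len(length(s) - 1))
      want[s[j] + 1, s[j + 1] + 1] <- want[s[j] + 1, s[j + 1] + 1] + 1L
  }
  expect_equal(unname(d$transition_counts), want)
  # row-stochastic on non-absorbing rows; endpoint vectors on the simplex
  rs <- rowSums(d$transition_probs)
  expect_true(all(abs(rs[!d$absorbing] - 1) < 1e-12))
  expect_equal(sum(d$init_probs), 1)
  expect_equal(sum(d$final_probs), 1)
  # invariant to path input order
  perm <- sample(length(paths))
  d2 <- build_diagram(make_paths(paths[perm],
                                 patients = sprintf("p%d", perm),
                                 ranks = rep(1L, length(paths))),
                      make_states(lab))
  expect_equal(d2$transition_counts, d$transition_counts)
})

test_that("endpoint probabilities come from first and last observed visits", {
  # one patient with two transitions a->b->c (as two paths)
  ids <- c("a", "b", "c")
  states <- make_states(setNames(c(0L, 1L, 2L), ids))
  paths <- make_paths(list(c("a", "b"), c("b", "c")),
                      patients = c("p1", "p1"), ranks = 1:2)
  d <- build_diagram(paths, states)
  expect_equal(d$init_probs, c(1, 0, 0))
  expect_equal(d$final_probs, c(0, 0, 1))
})

test_that("trajectory ranking scores and orders exactly", {
  # two-state chain: single possible walk
  d <- trajflow:::new_state_diagram(matrix(c(0L, 1L, 0L, 0L), 2, 2,
                                           byrow = TRUE,
                                           dimnames = list(0:1, 0:1)),
                                    init = c(1, 0), final = c(0, 1))
  tr <- top_trajectories(d, length = 1, k = 3)
  expect_equal(tr$states[1], "0-1")
  expect_equal(tr$score[1], 1)

  # uniform diagram: all sequences tie; top-k is the lexicographic prefix
  K <- 3
  cnt <- matrix(1L, K, K, dimnames = list(0:2, 0:2)); diag(cnt) <- 0L
  du <- trajflow:::new_state_diagram(cnt, rep(1 / K, K), rep(1 / K, K))
  tru <- top_trajectories(du, length = 2, k = 4)
  expect_equal(tru$states, c("0-1-0", "0-1-2", "0-2-0", "0-2-1"))
  expect_true(all(abs(diff(tru$score)) < 1e-12))

  # random 6-state diagram vs exhaustive scoring of all 6*5^3 sequences
  set.seed(23)
  cnt6 <- matrix(rpois(36, 3), 6, 6, dimnames = list(0:5, 0:5))
  diag(cnt6) <- 0L
  init <- runif(6); init <- init / sum(init)
  final <- runif(6); final <- final / sum(final)
  d6 <- trajflow:::new_state_diagram(cnt6, init, final)
  tr6 <- top_trajectories(d6, length = 3, k = 8)
  P <- d6$transition_probs
  all_scores <- c(); all_keys <- c()
  for (a in 0:5) for (b in 0:5) for (cc in 0:5) for (e in 0:5) {
    if (a == b || b == cc || cc == e) next
    all_keys <- c(all_keys, paste(a, b, cc, e, sep = "-"))
    all_scores <- c(all_scores,
                    init[a + 1] * P[a + 1, b + 1] * P[b + 1, cc + 1] *
                      P[cc + 1, e + 1] * final[e + 1])
  }
  ord <- order(-all_scores, all_keys)
  expect_equal(tr6$states, all_keys[ord][1:8])
  expect_equal(tr6$score, all_scores[ord][1:8], tolerance = 1e-12)

  # enumeration budget guard
  dbig <- trajflow:::new_state_diagram(
    matrix(1L, 12, 12, dimnames = list(0:11, 0:11)),
    rep(1 / 12, 12), rep(1 / 12, 12))
  expect_error(top_trajectories(dbig, length = 10, k = 1), "enumeration")
})

test_that("trajectory scores form a sub-distribution", {
  set.seed(31)
  cnt <- matrix(rpois(25, 2), 5, 5, dimnames = list(0:4, 0:4))
  diag(cnt) <- 0L
  init <- runif(5); init <- init / sum(init)
  final <- runif(5); final <- final / sum(final)
  d <- trajflow:::new_state_diagram(cnt, init, final)
  tr <- top_trajectories(d, length = 3, k = 5 * 4^3)
  final_of <- as.integer(sub(".*-", "", tr$states)) + 1
  expect_lte(sum(tr$score / final[final_of]), 1 + 1e-9)
})

test_that("subsequence redundancy is annotated, not filtered", {
  # deterministic chain 0->1->2->3 plus a skip edge 0->2
  cnt <- matrix(0L, 4, 4, dimnames = list(0:3, 0:3))
  cnt[1, 2] <- 8L; cnt[2, 3] <- 9L; cnt[3, 4] <- 9L; cnt[1, 3] <- 2L
  d <- trajflow:::new_state_diagram(cnt, c(1, 0, 0, 0), c(0, 0, 0, 1))
  tr3 <- top_trajectories(d, length = 3, k = 10)
  tr2 <- top_trajectories(d, length = 2, k = 10)
  expect_equal(tr3$states[1], "0-1-2-3")
  expect_equal(tr2$states[1], "0-2-3")  # subsequence of the length-3 winner
  # within one list: 0-2-3 never outranks 0-1-2-3 at equal length, but the
  # annotation marks later entries contained in earlier ones
  expect_true(all(is.na(tr3$subsequence_of) | tr3$subsequence_of < tr3$rank))
})

test_that("pruning keeps the smallest prefix reaching the mass and is idempotent", {
  cnt <- matrix(0L, 4, 4, dimnames = list(0:3, 0:3))
  cnt[1, 2:4] <- c(6L, 3L, 1L)       # weights 0.6 / 0.3 / 0.1
  cnt[2, c(1, 3, 4)] <- c(4L, 4L, 2L)  # weights 0.4 / 0.4 / 0.2
  d <- trajflow:::new_state_diagram(cnt, c(1, 0, 0, 0), c(0, 0, 0, 1))
  p <- prune_diagram(d, 0.5)
  expect_equal(unname(p$transition_probs[1, ]), c(0, 1, 0, 0))       # top edge only
  expect_equal(unname(p$transition_probs[2, ]), c(0.5, 0, 0.5, 0))   # both 0.4s
  expect_equal(prune_diagram(p, 0.5)$transition_probs, p$transition_probs)

  # random diagrams vs a brute-force prefix search per node
  set.seed(41)
  for (rep in 1:5) {
    cntr <- matrix(rpois(36, 2), 6, 6, dimnames = list(0:5, 0:5))
    diag(cntr) <- 0L
    dr <- trajflow:::new_state_diagram(cntr, rep(1/6, 6), rep(1/6, 6))
    mass <- runif(1, 0.2, 0.9)
    pr <- prune_diagram(dr, mass)
    for (s in 1:6) {
      w <- cntr[s, ]
      if (sum(w) == 0) { expect_true(all(pr$transition_probs[s, ] == 0)); next }
      ord <- order(-w, 1:6)
      ord <- ord[w[ord] > 0]
      kmin <- which(cumsum(w[ord]) >= mass * sum(w))[1]
      keep <- ord[seq_len(kmin)]
      expect_identical(unname(which(pr$transition_probs[s, ] > 0)), sort(keep))
    }
  }
})

test_that("diagram exports are readable", {
  cnt <- matrix(c(0L, 2L, 1L, 0L), 2, 2, byrow = TRUE,
                dimnames = list(0:1, 0:1))
  d <- trajflow:::new_state_diagram(cnt, c(1, 0), c(0, 1))
  fj <- tempfile(fileext = ".json")
  write_diagram_json(d, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$n_states, 2)
  expect_equal(back$transition_counts, unname(cnt))
  fd <- tempfile(fileext = ".dot")
  write_diagram_dot(d, fd)
  expect_match(readLines(fd)[1], "digraph")
})
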