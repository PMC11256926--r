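# Single reusable toy instance: unique path s-a-t.
path_instance <- function() {
  g <- flow_graph(data.frame(from = c("s", "a"), to = c("a", "t"), cost = 1))
  comm <- data.frame(id = 1L, source = "s", sink = "t", demand = 1,
                     patient_id = "p1", transition_rank = 1L)
  class(comm) <- c("CommoditySet", "data.frame")
  list(g = g, comm = comm)
}

test_that("a unique path at unit capacities carries the full demand", {
  pi <- path_instance()
  sol <- solve_flow(pi$g, pi$comm,
                    capacity_config(edge_capacity = 1, node_capacity = 1))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 2, tolerance = 1e-7)
  f <- sol$flows[order(sol$flows$from), ]
  expect_equal(f$flow, c(1, 1), tolerance = 1e-7)
  expect_equal(f$from, c("a", "s"))
})

test_that("uncapacitated single-commodity optimum equals the Dijkstra distance", {
  for (seed in 1:10) {
    inst <- random_flow_instance(n = sample(10:25, 1), m = 40, seed = seed)
    sol <- solve_flow(inst$graph, inst$commodities,
                      capacity_config(edge_capacity = Inf))
    want <- dijkstra_cost(inst, inst$commodities$source, inst$commodities$sink)
    expect_equal(sol$objective, want, tolerance = 1e-6)
    # and the extracted path is a real path of that cost
    p <- extract_paths(sol, inst$graph)
    expect_equal(p$cost[1], want, tolerance = 1e-6)
    expect_identical(p$nodes[[1]][1], inst$commodities$source)
    expect_identical(p$nodes[[1]][length(p$nodes[[1]])], inst$commodities$sink)
    expect_false(anyDuplicated(p$nodes[[1]]) > 0)
  }
})

test_that("capacity forces the second commodity onto a costlier route", {
  # two parallel routes s->m->t (cheap) and s->x->t (extra cost delta);
  # both commodities want the cheap middle route but C = 1 allows only one.
  delta <- 0.7
  edges <- data.frame(from = c("s1", "s2", "m", "s1", "s2", "x"),
                      to = c("m", "m", "t", "x", "x", "t"),
                      cost = c(1, 1, 1, 1, 1, 1 + delta))
  g <- flow_graph(edges)
  comm <- data.frame(id = 1:2, source = c("s1", "s2"), sink = "t", demand = 1,
                     patient_id = c("p1", "p2"), transition_rank = 1L)
  class(comm) <- c("CommoditySet", "data.frame")
  un <- solve_flow(g, comm, capacity_config(edge_capacity = Inf))
  cap <- solve_flow(g, comm, capacity_config(edge_capacity = 1))
  expect_equal(cap$objective, un$objective + delta, tolerance = 1e-6)
  # exhaustive integral routing confirms optimality
  inst <- list(edges = edges, ids = g$nodes,
               commodities = comm)
  bf <- brute_force_mcf(inst, C = 1)
  expect_true(bf$feasible)
  expect_equal(cap$objective, bf$cost, tolerance = 1e-6)
})

test_that("solved instances satisfy conservation and capacity residuals", {
  for (seed in 1:8) {
    inst <- random_flow_instance(n = 15, m = 30, seed = 100 + seed, n_comm = 4)
    sol <- solve_flow(inst$graph, inst$commodities,
                      capacity_config(edge_capacity = 2, node_capacity = 3))
    if (sol$status != "optimal") next
    res <- verify_flow_solution(sol, inst$graph)
    expect_lt(res$conservation, 1e-6)
    expect_lt(res$edge_capacity, 1e-6)
    expect_lt(res$node_capacity, 1e-6)
  }
})

test_that("relaxing capacities never raises the optimum", {
  inst <- random_flow_instance(n = 12, m = 24, seed = 55, n_comm = 3)
  obj <- function(C, N) {
    s <- solve_flow(inst$graph, inst$commodities,
                    capacity_config(edge_capacity = C, node_capacity = N))
    if (s$status == "optimal") s$objective else Inf
  }
  u_inf <- obj(Inf, Inf)
  expect_true(obj(1, Inf) + 1e-9 >= obj(2, Inf))
  expect_true(obj(2, Inf) + 1e-9 >= u_inf)
  expect_true(obj(Inf, 2) + 1e-9 >= u_inf)
  expect_true(obj(Inf, 1) + 1e-9 >= obj(Inf, 2))
})

test_that("infeasible instances return a status and a capacity suggestion", {
  # two commodities into the same sink node through a single shared arc
  edges <- data.frame(from = c("s1", "s2", "m"), to = c("m", "m", "t"), cost = 1)
  g <- flow_graph(edges)
  comm <- data.frame(id = 1:2, source = c("s1", "s2"), sink = "t", demand = 1,
                     patient_id = c("p1", "p2"), transition_rank = 1L)
  class(comm) <- c("CommoditySet", "data.frame")
  sol <- solve_flow(g, comm, capacity_config(edge_capacity = 1))
  expect_equal(sol$status, "infeasible")
  expect_match(sol$diagnostic, "larger C")
  expect_error(extract_paths(sol, g), "infeasible")
  # doubling the capacity resolves it
  sol2 <- solve_flow(g, comm, capacity_config(edge_capacity = 2))
  expect_equal(sol2$status, "optimal")
})

test_that("fractional optimum never exceeds the best integral routing", {
  for (seed in 1:6) {
    inst <- random_flow_instance(n = 7, m = 12, seed = 200 + seed, n_comm = 2)
    lp <- solve_flow(inst$graph, inst$commodities,
                     capacity_config(edge_capacity = 1))
    bf <- brute_force_mcf(inst, C = 1)
    if (lp$status == "optimal") {
      expect_lte(lp$objective, bf$cost + 1e-6)
      integral <- all(abs(lp$flows$flow - round(lp$flows$flow)) < 1e-7)
      if (integral && bf$feasible)
        expect_equal(lp$objective, bf$cost, tolerance = 1e-6)
    }
  }
})

test_that("hop restriction at or beyond the diameter leaves the optimum unchanged", {
  for (seed in c(3, 4)) {
    inst <- random_flow_instance(n = 12, m = 22, seed = seed, n_comm = 2)
    free <- solve_flow(inst$graph, inst$commodities,
                       capacity_config(edge_capacity = Inf))
    lim <- solve_flow(inst$graph, inst$commodities,
                      capacity_config(edge_capacity = Inf,
                                      hop_limit = length(inst$ids)))
    expect_equal(lim$objective, free$objective, tolerance = 1e-6)
  }
})

test_that("path extraction decomposes fractional flows into weighted paths", {
  pi <- path_instance()
  sol <- solve_flow(pi$g, pi$comm, capacity_config(edge_capacity = Inf))
  p <- extract_paths(sol, pi$g)
  expect_identical(p$nodes[[1]], c("s", "a", "t"))

  # hand-built 0.5/0.5 split over two equal-cost routes: the lexicographically
  # smaller node sequence must be returned
  g2 <- flow_graph(data.frame(from = c("s", "s", "a", "b"),
                              to = c("a", "b", "t", "t"), cost = 1))
  comm <- data.frame(id = 1L, source = "s", sink = "t", demand = 1,
                     patient_id = "p1", transition_rank = 1L)
  class(comm) <- c("CommoditySet", "data.frame")
  sol2 <- structure(list(
    status = "optimal", objective = 2,
    flows = data.frame(commodity_id = 1L,
                       from = c("s", "s", "a", "b"),
                       to = c("a", "b", "t", "t"),
                       flow = rep(0.5, 4)),
    commodities = comm, cfg = capacity_config(edge_capacity = Inf)),
    class = "FlowSolution")
  p2 <- extract_paths(sol2, g2, tau = 0.6)
  expect_identical(p2$nodes[[1]], c("s", "a", "t"))
  expect_equal(p2$weight, 0.5)

  # random fractional flows: decomposition weights account for the demand
  set.seed(8)
  for (rep in 1:5) {
    inst <- random_flow_instance(n = 10, m = 18, seed = 300 + rep)
    sol3 <- solve_flow(inst$graph, inst$commodities,
                       capacity_config(edge_capacity = Inf))
    f <- sol3$flows
    dec <- trajflow:::decompose_flow(f, inst$commodities$source,
                                     inst$commodities$sink)
    expect_equal(sum(dec$weights), 1, tolerance = 1e-6)
  }
})

test_that("flow solution and path exports round-trip through disk", {
  pi <- path_instance()
  sol <- solve_flow(pi$g, pi$comm, capacity_config(edge_capacity = 1))
  fj <- tempfile(fileext = ".json")
  write_flow_json(sol, fj)
  back <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(back$objective, sol$objective)
  expect_equal(back$status, "optimal")
  pt <- tempfile(fileext = ".tsv")
  write_paths_tsv(extract_paths(sol, pi$g), pt)
  df <- read.delim(pt)
  expect_identical(df$nodes, "s,a,t")
})
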