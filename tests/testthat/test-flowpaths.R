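test_that("diamond DAG has two paths, one through each middle edge", {
  edges <- data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4),
                      len = 1)
  dag <- dag_from_edges(edges, sources = 1, sinks = 4)
  pc <- count_paths(dag)
  expect_equal(pc$total, 2)
  expect_equal(unname(pc$edge_paths), c(1, 1, 1, 1))
})

test_that("ladder path counts follow the closed-form recurrence", {
  # k independent 3-segment rungs between two rails: exactly k paths
  for (k in c(2, 4, 6)) {
    g <- ladder_fixture(k)
    g$vessels$type[1] <- "DA"; g$vessels$main_branch[1] <- TRUE
    nv <- nrow(g$vessels)
    g$vessels$type[nv] <- "AV"; g$vessels$main_branch[nv] <- TRUE
    bc <- boundary_conditions(g$nodes$id[g$nodes$is_boundary], c(40, 15),
                              unit = "mmHg")
    fl <- solve_pressure_flow(g, bc)
    pc <- count_paths(build_flow_dag(g, fl))
    expect_equal(pc$total, k)
  }
})

test_that("DP counts equal exhaustive enumeration on random DAGs", {
  n_fail <- 0
  for (seed in 1:500) {
    edges <- random_dag(n_nodes = 10, n_edges = sample(5:30, 1), seed = seed)
    sources <- unique(edges$from[!(edges$from %in% edges$to)])
    sinks <- unique(edges$to[!(edges$to %in% edges$from)])
    if (!length(sources) || !length(sinks)) next
    dag <- dag_from_edges(edges, sources, sinks)
    pc <- count_paths(dag)
    brute <- length(oracle_enumerate_paths(edges, sources, sinks))
    if (!isTRUE(all.equal(pc$total, brute))) n_fail <- n_fail + 1
    # per-edge identity U(tail) x W(head)
    u <- pc$U[as.character(dag$edges$from)]
    w <- pc$W[as.character(dag$edges$to)]
    if (!isTRUE(all.equal(unname(u * w), unname(pc$edge_paths)))) {
      n_fail <- n_fail + 1
    }
  }
  expect_equal(n_fail, 0)
})

test_that("zero-flow tolerance above max |q| empties the DAG", {
  m <- make_msc_motif("1-1")
  fl <- solve_pressure_flow(m$graph, m$bc)
  dag <- build_flow_dag(m$graph, fl, q_eps = max(abs(fl$q)) * 2)
  expect_equal(nrow(dag$edges), 0L)
})

test_that("endpoints sit at the first branch point after the main branch", {
  # trunk 1-2 (main), offshoot 2-3, first branch node 3 with two capillaries
  nodes <- data.frame(id = 1:5, x = c(0, 0, 0, 50, -50),
                      y = c(0, 0, 0, 50, 50), z = c(0, 100, 180, 260, 260),
                      is_boundary = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  vessels <- data.frame(id = 1:4, source = c(1, 2, 3, 3),
                        target = c(2, 3, 4, 5),
                        diameter = c(12, 6.5, 4, 4), length = c(100, 80, 95, 95),
                        type = c("DA", "DA", "C", "C"),
                        main_branch = c(TRUE, FALSE, FALSE, FALSE))
  g <- mvn_graph(nodes, vessels)
  expect_equal(mvnstroke:::tree_endpoints(g, "DA"), 3L)
})

test_that("pair analysis classifies and tallies endpoint pairs", {
  # bridge pair: occluding the only connecting path loses the pair
  sl <- shared_lattice()
  g <- sl$net$graph
  dag_base <- build_flow_dag(g, sl$flow)
  sel <- select_msc_candidates(g, sl$flow)
  inc <- mvnstroke:::incidence_list(g)
  types <- vapply(sel$candidates, function(v)
    classify_msc_type(g, sl$flow, v, inc = inc), character(1))
  msc <- sel$candidates[which(types == "2-2")][1]
  fl_stroke <- solve_pressure_flow(occlude(g, msc), sl$net$bc)
  dag_stroke <- build_flow_dag(g, fl_stroke)
  pa <- pair_analysis(dag_base, dag_stroke, g, msc)
  p <- pa$pairs
  expect_true(all(p$category %in% c("cat1", "cat2", "excluded")))
  # cat1 pairs have baseline paths through the MSC, cat2 pairs do not
  expect_true(all(p$through_msc_base[p$category == "cat1"] > 0))
  expect_true(all(p$through_msc_base[p$category == "cat2"] == 0))
  # category tallies cover all baseline-or-stroke connected pairs
  n_conn <- sum(p$n_base > 0 | p$n_stroke > 0)
  expect_equal(nrow(p), n_conn)
  # per-pair counts agree with brute-force enumeration for a few pairs
  edges <- dag_base$edges
  edges$len <- 1
  few <- head(which(p$n_base > 0 & p$n_base < 5000), 3)
  for (i in few) {
    brute <- length(oracle_enumerate_paths(edges[, c("from", "to", "len")],
                                           sources = p$da[i],
                                           sinks = p$av[i]))
    expect_equal(p$n_base[i], brute)
  }
})

test_that("per-vessel path counts drop when their carrier is occluded", {
  m <- make_msc_motif("2-2")
  g <- m$graph
  g$vessels$type[1] <- "DA"; g$vessels$main_branch[1] <- TRUE
  g$vessels$type[2] <- "AV"; g$vessels$main_branch[2] <- TRUE
  fl <- solve_pressure_flow(g, m$bc)
  pc_base <- count_paths(build_flow_dag(g, fl))
  fl2 <- solve_pressure_flow(occlude(g, m$msc), m$bc)
  pc_stroke <- count_paths(build_flow_dag(g, fl2))
  n_msc <- pc_stroke$edge_paths[as.character(m$msc)]
  expect_lt(ifelse(is.na(n_msc), 0, n_msc), 1)
  expect_gt(pc_base$total, 0)
})
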