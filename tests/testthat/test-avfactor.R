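# marks a ladder fixture as penetrating trees so flow-path endpoints exist:
# the feed vessel becomes the DA main branch and the drain the AV main branch
ladder_with_trees <- function(k = 3) {
  g <- ladder_fixture(k)
  g$vessels$type[1] <- "DA"
  g$vessels$main_branch[1] <- TRUE
  nv <- nrow(g$vessels)
  g$vessels$type[nv] <- "AV"
  g$vessels$main_branch[nv] <- TRUE
  bc <- boundary_conditions(g$nodes$id[g$nodes$is_boundary], c(40, 15),
                            unit = "mmHg")
  fl <- solve_pressure_flow(g, bc)
  list(graph = g, bc = bc, flow = fl)
}

test_that("centerline discretization has the promised point counts", {
  g <- tube_graph(d = 5, len = 13)
  d <- discretize(g, spacing = 1.3)
  expect_equal(nrow(d$points), 11L)
  sp <- sqrt(rowSums(diff(d$points)^2))
  expect_true(all(sp <= 1.3 + 1e-9))
  # resampled tortuous polyline preserves the arc length within 1%
  m <- make_msc_motif("1-1")
  dd <- discretize(m$graph)
  for (vid in m$graph$vessels$id[1:5]) {
    pts <- dd$points[dd$vessel == vid, ]
    L <- sum(sqrt(rowSums(diff(pts)^2)))
    expect_equal(L, m$graph$vessels$length[match(vid, m$graph$vessels$id)],
                 tolerance = 0.01)
  }
  # total point count grows linearly with total length
  expect_equal(nrow(dd$points),
               sum(ceiling(m$graph$vessels$length / 1.3) + 1))
})

test_that("AV-factor is 0.5 on a mirror-symmetric ladder and lies in [0,1]", {
  lw <- ladder_with_trees(3)
  av <- compute_av_factor(lw$graph, lw$flow)
  # the middle segment of every rung is equidistant from both endpoint sets
  mids <- av$av_factor[av$med_da > 0 & av$med_av > 0 & !is.na(av$av_factor)]
  expect_true(length(mids) >= 3)
  expect_true(all(abs(mids - 0.5) < 1e-9))
  sl <- shared_lattice()
  av2 <- compute_av_factor(sl$net$graph, sl$flow, n_sample = 500)
  ok <- !is.na(av2$av_factor)
  expect_true(any(ok))
  expect_true(all(av2$av_factor[ok] >= 0 & av2$av_factor[ok] <= 1))
})

test_that("AV-factor increases monotonically along an unbranched chain", {
  g <- chain_graph(rep(5, 7))
  g$vessels$type <- c("DA", rep("C", 5), "AV")
  g$vessels$main_branch <- c(TRUE, rep(FALSE, 5), TRUE)
  bc <- boundary_conditions(c(1, 8), c(40, 15), unit = "mmHg")
  fl <- solve_pressure_flow(g, bc)
  av <- compute_av_factor(g, fl)
  vals <- av$av_factor[!is.na(av$av_factor)]
  expect_true(all(diff(vals) > 0))
})

test_that("medians match exhaustive enumeration on a small fixture", {
  m <- make_msc_motif("2-2")
  g <- m$graph
  g$vessels$type[1] <- "DA"; g$vessels$main_branch[1] <- TRUE
  g$vessels$type[2] <- "AV"; g$vessels$main_branch[2] <- TRUE
  fl <- solve_pressure_flow(g, m$bc)
  dag <- build_flow_dag(g, fl)
  av <- compute_av_factor(g, fl, dag = dag)
  # oracle: exhaustive DFS on the oriented edge list
  edges <- dag$edges
  edges$len <- g$vessels$length[match(edges$vessel, g$vessels$id)]
  redges <- data.frame(from = edges$to, to = edges$from, len = edges$len)
  for (r in which(!is.na(av$av_factor))[1:5]) {
    vid <- av$vessel[r]
    ei <- match(vid, edges$vessel)
    up <- oracle_enumerate_paths(redges[, c("from", "to", "len")] |>
                                   (\(d) {names(d) <- c("from", "to", "len"); d})(),
                                 sources = edges$from[ei],
                                 sinks = dag$da_endpoints)
    dn <- oracle_enumerate_paths(edges[, c("from", "to", "len")],
                                 sources = edges$to[ei],
                                 sinks = dag$av_endpoints)
    expect_equal(av$med_da[r], stats::median(up), tolerance = 1e-9)
    expect_equal(av$med_av[r], stats::median(dn), tolerance = 1e-9)
  }
})

test_that("path sampling converges to the exhaustive medians", {
  sl <- shared_lattice()
  g <- sl$net$graph
  dag <- build_flow_dag(g, sl$flow)
  exact <- compute_av_factor(g, sl$flow, dag = dag, max_paths = 1e6,
                             n_sample = 10)
  approx <- compute_av_factor(g, sl$flow, dag = dag, max_paths = 50,
                              n_sample = 4000, seed = 3)
  both <- !is.na(exact$av_factor) & !is.na(approx$av_factor) & approx$sampled
  expect_gt(sum(both), 10)
  err <- abs(exact$av_factor[both] - approx$av_factor[both])
  expect_lt(stats::median(err), 0.05)
})

test_that("distance maps match plane geometry and brute force", {
  # two parallel vessels 20 um apart, one arteriole-sided one venule-sided
  n <- data.frame(id = 1:4, x = c(0, 100, 0, 100), y = c(0, 0, 20, 20),
                  z = 0, is_boundary = TRUE)
  v <- data.frame(id = 1:2, source = c(1, 3), target = c(2, 4), diameter = 5,
                  length = 100, type = "C", main_branch = FALSE)
  g <- mvn_graph(n, v)
  disc <- discretize(g, spacing = 1)
  avmap <- data.frame(vessel = 1:2, av_factor = c(0.2, 0.8))
  dm <- distance_maps(disc, avmap)
  expect_true(all(dm$vessel == 2))
  mid <- which.min(abs(disc$points[disc$vessel == 2, 1] - 50))
  expect_equal(dm$d_arteriole[mid], 20, tolerance = 1e-9)
  expect_equal(dm$d_any[mid], 20, tolerance = 1e-9)
  expect_equal(dm$distance_factor[mid], 1, tolerance = 1e-9)
})

test_that("sphere and cube scans respect their eligibility rules", {
  lw <- ladder_with_trees(4)
  av <- compute_av_factor(lw$graph, lw$flow)
  disc <- discretize(lw$graph)
  ss <- sphere_scan(lw$graph, av, disc, r = 50)
  # all assigned capillaries have AV-factor 0.5 -> every eligible sphere
  # mean is 0.5 and the difference is 0
  el <- ss$eligible
  expect_true(any(el))
  # brute-force oracle for one capillary
  k <- which(el)[1]
  centers <- disc$points[disc$vessel == ss$vessel[k], , drop = FALSE]
  capav <- av$av_factor[match(disc$vessel, av$vessel)]
  inside <- rep(FALSE, nrow(disc$points))
  for (c_ in seq_len(nrow(centers))) {
    dd <- sqrt(colSums((t(disc$points) - centers[c_, ])^2))
    inside <- inside | dd <= 50
  }
  expect_equal(ss$sphere_mean[k],
               mean(capav[inside], na.rm = TRUE), tolerance = 1e-9)

  cs <- cube_scan(lw$graph, av, disc, side = 60, min_capillaries = 4)
  expect_true(all(!cs$eligible | cs$n_with_av >= 4))
  # a cube requirement above the capillary count disqualifies everything
  cs2 <- cube_scan(lw$graph, av, disc, side = 60, min_capillaries = 99)
  expect_false(any(cs2$eligible))
})
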