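test_that("occlusion drives the MSC flow to numerical zero and reverses", {
  m <- make_msc_motif("2-2")
  g_occ <- occlude(m$graph, m$msc)
  fl <- solve_pressure_flow(g_occ, m$bc)
  expect_lte(abs(fl$q[m$msc]), 1e-10)
  # empty id list leaves the graph untouched
  expect_identical(occlude(m$graph, integer(0)), m$graph)
  # occlusion + restoration is an exact involution
  g_back <- restore_occlusion(g_occ)
  expect_equal(g_back$vessels$diameter, m$graph$vessels$diameter)
  fl0 <- solve_pressure_flow(m$graph, m$bc)
  fl_back <- solve_pressure_flow(g_back, m$bc)
  expect_identical(fl_back$q, fl0$q)
})

test_that("thresholded relative change follows the printed formula", {
  expect_equal(thresholded_relative_change(1.0, 0.3, 0.1), -0.7)
  expect_equal(thresholded_relative_change(1.0, 0.95, 0.1), 0)
  expect_equal(thresholded_relative_change(1.0, -1.0, 0.1), 0)
  expect_true(is.na(thresholded_relative_change(0, 1, 0.1)))
  # property check against the direct formula on random inputs
  qb <- with_seed_test(5, stats::runif(500, -10, 10))
  qs <- with_seed_test(6, stats::runif(500, -10, 10))
  got <- thresholded_relative_change(qb, qs, 0.1)
  expected <- ifelse(abs(abs(qs) - abs(qb)) < 0.1, 0,
                     (abs(qs) - abs(qb)) / abs(qb))
  expect_equal(got, expected)
})

test_that("candidate selection applies criteria conjunctively and counts
           survivors per stage", {
  sl <- shared_lattice()
  g <- sl$net$graph
  # all criteria disabled: every capillary is returned
  sel0 <- select_msc_candidates(g, sl$flow, criteria = integer(0))
  expect_equal(sort(sel0$candidates), sort(g$vessels$id[g$vessels$type == "C"]))
  sel <- select_msc_candidates(g, sl$flow)
  expect_true(all(diff(sel$counts) <= 0))   # criteria only remove
  # tightening the flow threshold never adds candidates
  sel_tight <- select_msc_candidates(g, sl$flow,
                                     stroke_config(min_flow = 0.5))
  expect_true(all(sel_tight$candidates %in% sel$candidates))
  # a capillary violating only the flow criterion is dropped at that stage
  low <- sel$candidates[1]
  fl2 <- sl$flow
  fl2$q[match(low, g$vessels$id)] <- 0.01
  sel2 <- select_msc_candidates(g, fl2)
  expect_false(low %in% sel2$candidates)
  expect_equal(unname(sel2$counts["cylinder"] - sel2$counts["min_flow"]),
               unname(sel$counts["cylinder"] - sel$counts["min_flow"]) + 1)
})

test_that("selection set is independent of criterion order", {
  sl <- shared_lattice()
  sel_a <- select_msc_candidates(sl$net$graph, sl$flow, criteria = c(1, 2, 5, 6))
  sel_b <- select_msc_candidates(sl$net$graph, sl$flow, criteria = c(6, 5, 2, 1))
  expect_setequal(sel_a$candidates, sel_b$candidates)
})

test_that("stroke severity ranks 2-2 above 1-1 on matched motifs", {
  res <- lapply(c("2-2", "1-1"), function(ty) {
    m <- make_msc_motif(ty)
    run_single_stroke(m$graph, m$bc, m$msc, mode = "steady")
  })
  dq1 <- sapply(res, function(s) {
    g1 <- s$generations$vessel[abs(s$generations$generation) == 1]
    mean(abs(s$dq[g1]))
  })
  expect_gt(dq1[1], dq1[2])
  # occluding a vessel with ~zero baseline flow changes nothing above
  # threshold
  sl <- shared_lattice()
  g <- sl$net$graph
  qabs <- abs(sl$flow$q)
  dead <- g$vessels$id[which(g$vessels$type == "C" & qabs < 1e-6)][1]
  s0 <- run_single_stroke(g, sl$net$bc, dead, mode = "steady",
                          baseline = sl$flow)
  expect_true(all(s0$dq[!is.na(s0$dq)] == 0))
})

test_that("steady and RBC modes agree on the signs at generation ±1", {
  m <- make_msc_motif("2-2")
  s_st <- run_single_stroke(m$graph, m$bc, m$msc, mode = "steady")
  s_rbc <- run_single_stroke(m$graph, m$bc, m$msc, mode = "rbc", seed = 1,
                             n_turnovers = 3)
  g1 <- s_st$generations$vessel[abs(s_st$generations$generation) == 1]
  expect_equal(sign(s_st$dq[g1]), sign(s_rbc$dq[g1]))
})

test_that("sequential multi-occlusion follows the 1,3,5,7,9 protocol", {
  sl <- shared_lattice()
  g <- sl$net$graph
  sel <- select_msc_candidates(g, sl$flow)
  inc <- mvnstroke:::incidence_list(g)
  types <- vapply(sel$candidates, function(v)
    classify_msc_type(g, sl$flow, v, inc = inc), character(1))
  # as in the protocol, only MSCs with enough capillaries in the box qualify
  stages <- NULL
  for (msc in sel$candidates[which(types == "2-2")]) {
    stages <- tryCatch(suppressWarnings(
      run_multi_occlusion(g, sl$net$bc, msc, box_volume = nl_to_um3(1.5))),
      error = function(e) NULL)
    if (!is.null(stages)) break
  }
  expect_false(is.null(stages))
  expect_equal(sapply(stages, `[[`, "n_occluded"), c(1, 3, 5, 7, 9))
  for (st in stages) {
    expect_true(all(abs(st$stroke$q[st$occluded]) <= 1e-10))
  }
  expect_false(attr(stages, "stopped_early"))
  # early stop: target unreachable with a tiny candidate pool
  expect_error(run_multi_occlusion(g, sl$net$bc, msc,
                                   box_volume = nl_to_um3(0.05)),
               "capillaries")
})

test_that("main-branch distance counts segments to the trunk", {
  # trunk t1 at nodes 1-2, then a chain of capillaries
  nodes <- data.frame(id = 1:5, x = 0, y = 0, z = c(0, 80, 160, 240, 320),
                      is_boundary = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  vessels <- data.frame(id = 1:4, source = 1:4, target = 2:5,
                        diameter = c(12, 6.5, 4, 4), length = 80,
                        type = c("DA", "DA", "C", "C"),
                        main_branch = c(TRUE, FALSE, FALSE, FALSE))
  g <- mvn_graph(nodes, vessels)
  d <- main_branch_distance(g)
  expect_equal(d, c(0, 1, 2, 3))
})
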