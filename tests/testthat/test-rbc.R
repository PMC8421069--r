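test_that("RBC-free simulation equals the steady solve exactly", {
  m <- make_msc_motif("1-1", inflow_hematocrit = 0)
  av <- run_and_average(m$graph, m$bc, n_turnovers = 2, seed = 1)
  st <- solve_pressure_flow(m$graph, m$bc, h_d = 0)
  expect_equal(av$mean_q, st$q, tolerance = 1e-12)
  expect_true(all(av$dirchange == 0))
})

test_that("a single perfused tube transports RBCs at the cell velocity", {
  g <- tube_graph(d = 8, len = 100)
  bc <- boundary_conditions(1:2, c(50, 0), unit = "Pa", inflow_hematocrit = 0.3)
  state <- rbc_init(g, bc, seed = 1, prefill = FALSE)
  state <- rbc_step(state, dt = 0.5)
  flow <- state$flow
  v_bulk <- flow$q[1] / (pi * 8^2 / 4)
  ratio <- mvnstroke:::fahraeus_ratio(8, flow$h_d[1])
  v_rbc <- v_bulk / ratio
  expect_gt(v_rbc, v_bulk)    # cells outrun the bulk (Fahraeus)
  # run to steady injection and time one transit
  for (i in 1:50) state <- rbc_step(state, dt = 0.5)
  expect_gt(length(state$vessel), 0)
  transit <- 100 / v_rbc
  # a cell entering at 0 leaves after about L / v_rbc
  pos0 <- min(state$pos)
  steps_needed <- ceiling((100 - pos0) / (v_rbc * 0.5))
  expect_lt(steps_needed * 0.5, transit + 0.5 + 1)
})

test_that("the RBC ledger balances at every step", {
  m <- make_msc_motif("2-2")
  state <- rbc_init(m$graph, m$bc, seed = 3)
  n0 <- length(state$vessel)
  expect_equal(state$created, n0)
  for (i in 1:40) {
    state <- rbc_step(state)
    expect_equal(state$created - state$destroyed, length(state$vessel))
    expect_true(all(state$pos >= 0))
    expect_true(all(state$pos <= m$graph$vessels$length[state$vessel] + 1e-9))
  }
})

test_that("turnover time equals lumen volume over flow for a single tube", {
  g <- tube_graph(d = 8, len = 100)
  bc <- boundary_conditions(1:2, c(50, 0), unit = "Pa", inflow_hematocrit = 0)
  av <- run_and_average(g, bc, n_turnovers = 1, seed = 1)
  lumen <- pi * 8^2 / 4 * 100
  q <- abs(av$mean_q[1])
  # turnover detection is step-quantized: within one dt of the exact time
  expect_lt(abs(av$turnover - lumen / q), 1.01)
})

test_that("turnover scales inversely with the driving pressure", {
  g <- tube_graph(d = 8, len = 100)
  bc1 <- boundary_conditions(1:2, c(50, 0), unit = "Pa", inflow_hematocrit = 0)
  bc2 <- boundary_conditions(1:2, c(100, 0), unit = "Pa", inflow_hematocrit = 0)
  t1 <- run_and_average(g, bc1, n_turnovers = 1, seed = 1)$turnover
  t2 <- run_and_average(g, bc2, n_turnovers = 1, seed = 1)$turnover
  expect_equal(t1 / t2, 2, tolerance = 0.05)
})

test_that("identical seeds reproduce the time-averaged field exactly", {
  m <- make_msc_motif("2-1")
  a <- run_and_average(m$graph, m$bc, n_turnovers = 3, seed = 7)
  b <- run_and_average(m$graph, m$bc, n_turnovers = 3, seed = 7)
  expect_identical(a$mean_q, b$mean_q)
  expect_identical(a$mean_ht, b$mean_ht)
  expect_true(all(a$dirchange >= 0 & a$dirchange <= 1))
})

test_that("time-averaged fields conserve mass to within 1% of the inflow", {
  m <- make_msc_motif("2-2")
  av <- run_and_average(m$graph, m$bc, n_turnovers = 5, seed = 2)
  res <- continuity_residual(m$graph, av$mean_q)
  inflow <- abs(av$mean_q[1])
  expect_lt(max(abs(res)) / inflow, 0.01)
})

test_that("single-file routing follows the largest pressure force", {
  # two daughters: dp * area = 40 * pi/4*25 vs 10 * pi/4*49
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 200),
                      y = c(0, 0, 50, -50), z = 0,
                      is_boundary = c(TRUE, FALSE, TRUE, TRUE))
  vessels <- data.frame(id = 1:3, source = c(1, 2, 2), target = c(2, 3, 4),
                        diameter = c(8, 5, 7), length = 100)
  g <- mvn_graph(nodes, vessels)
  flow <- list(q = c(1, 0.5, 0.5),
               pressure = c(100, 50, 10, 40),
               h_d = c(0.3, 0.3, 0.3))
  # dp to node 3: 40 Pa with D = 5 -> force 40*25 = 1000 (up to pi/4)
  # dp to node 4: 10 Pa with D = 7 -> force 10*49 = 490
  pick <- select_daughter_single_file(g, flow, node = 2,
                                      daughters = c(2L, 3L))
  expect_equal(pick, 2L)
  # identical daughters: lowest vessel id wins
  flow2 <- list(q = c(1, 0.5, 0.5), pressure = c(100, 50, 10, 10),
                h_d = c(0.3, 0.3, 0.3))
  g2 <- g; g2$vessels$diameter <- c(8, 5, 5)
  expect_equal(select_daughter_single_file(g2, flow2, node = 2,
                                           daughters = c(2L, 3L)), 2L)
  # single outflow daughter: that daughter
  expect_equal(select_daughter_single_file(g, flow, node = 2,
                                           daughters = 3L), 3L)
})

test_that("two seeds give consistent averaged fields on a lattice", {
  net <- generate_lattice_mvn(generator_config(nx = 4, ny = 4, nz = 4,
                                               seed = 12))
  a <- run_and_average(net$graph, net$bc, n_turnovers = 2, seed = 1,
                       max_steps = 6000)
  b <- run_and_average(net$graph, net$bc, n_turnovers = 2, seed = 2,
                       max_steps = 6000)
  perf <- a$mean_abs_q > stats::median(a$mean_abs_q)
  rel <- abs(a$mean_abs_q[perf] - b$mean_abs_q[perf]) /
    pmax(a$mean_abs_q[perf], 1e-9)
  expect_lt(stats::median(rel), 0.10)
})
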