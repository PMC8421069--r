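test_that("validation reports structural problems and passes clean graphs", {
  g <- tube_graph()
  expect_equal(nrow(validate_graph(g)), 0L)

  g_bad <- tube_graph()
  g_bad$vessels$diameter[1] <- 0
  rep <- validate_graph(g_bad)
  expect_equal(sum(rep$level == "fatal"), 1L)
  expect_equal(rep$code[rep$level == "fatal"], "bad_diameter")

  # isolated node: warning finding
  n <- data.frame(id = 1:3, x = c(0, 100, 500), y = 0, z = 0,
                  is_boundary = c(TRUE, TRUE, FALSE))
  v <- data.frame(id = 1L, source = 1L, target = 2L, diameter = 5, length = 100)
  g_iso <- mvn_graph(n, v)
  rep <- validate_graph(g_iso)
  expect_true("isolated_node" %in% rep$code)
  expect_true(all(rep$level[rep$code == "isolated_node"] == "warning"))
})

test_that("constructor rejects dangling edge references", {
  n <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = 0)
  v <- data.frame(id = 1L, source = 1L, target = 9L, diameter = 5, length = 100)
  expect_error(mvn_graph(n, v), "missing node")
})

test_that("network I/O round-trips topology and attributes", {
  for (seed in c(1, 2, 3)) {
    net <- generate_lattice_mvn(generator_config(nx = 4, ny = 4, nz = 3,
                                                 seed = seed))
    dir <- withr::local_tempdir()
    write_network(net$graph, dir)
    g2 <- read_network(file.path(dir, "nodes.csv"), file.path(dir, "edges.csv"))
    expect_equal(g2$nodes$id, net$graph$nodes$id)
    expect_equal(g2$vessels$source, net$graph$vessels$source)
    expect_equal(g2$vessels$target, net$graph$vessels$target)
    expect_equal(g2$vessels$diameter, net$graph$vessels$diameter,
                 tolerance = 1e-12)
    expect_equal(g2$vessels$type, net$graph$vessels$type)
    expect_equal(g2$vessels$main_branch, net$graph$vessels$main_branch)
    i <- which.max(net$graph$vessels$length)
    expect_equal(g2$vessels$centerline[[i]],
                 unname(net$graph$vessels$centerline[[i]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # extra columns are preserved as opaque attributes
  dir <- withr::local_tempdir()
  g <- tube_graph()
  g$vessels$lab_note <- "stalled"
  write_network(g, dir)
  g2 <- read_network(file.path(dir, "nodes.csv"), file.path(dir, "edges.csv"))
  expect_equal(g2$vessels$lab_note, "stalled")
})

test_that("vessel-type assignment follows the consecutive-thin-pair rule", {
  run_chain <- function(diams) {
    g <- chain_graph(diams, z0 = 0)
    # descending chain: boundary node 1 at the surface is the DA root
    g$nodes$z <- (seq_len(nrow(g$nodes)) - 1) * 40
    g$vessels$type <- "DA"
    g <- assign_vessel_types(g)
    g$vessels$type
  }
  expect_equal(run_chain(c(9, 7, 5.5, 5.2, 4.8)), c("DA", "DA", "C", "C", "C"))
  expect_equal(run_chain(c(9, 5.5, 7, 5.2, 4.9)), c("DA", "DA", "DA", "C", "C"))
  expect_equal(run_chain(c(9, 8, 7, 6.5, 6.1)), rep("DA", 5))
})

test_that("vessel-type assignment is idempotent", {
  net <- generate_lattice_mvn(generator_config(nx = 4, ny = 4, nz = 4, seed = 5))
  g1 <- assign_vessel_types(net$graph)
  g2 <- assign_vessel_types(g1)
  expect_equal(g1$vessels$type, g2$vessels$type)
})

test_that("main-branch labeling keeps the trunk and skips short offshoots", {
  # straight descending trunk with one short lateral offshoot
  nodes <- data.frame(id = 1:5,
                      x = c(0, 0, 0, 60, 0), y = 0,
                      z = c(0, 80, 160, 170, 240),
                      is_boundary = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  vessels <- data.frame(id = 1:4, source = c(1, 2, 3, 3), target = c(2, 3, 4, 5),
                        diameter = c(12, 11, 7, 10), length = c(80, 80, 62, 80),
                        type = "DA", main_branch = FALSE)
  g <- mvn_graph(nodes, vessels)
  g <- split_main_branch(g)
  expect_equal(g$vessels$main_branch, c(TRUE, TRUE, FALSE, TRUE))

  # unbranched trunk: everything is main branch
  g2 <- chain_graph(c(12, 11, 10))
  g2$nodes$z <- c(0, 80, 160, 240)
  g2$vessels$type <- "DA"
  g2 <- split_main_branch(g2)
  expect_true(all(g2$vessels$main_branch))

  # symmetric Y: equal angles and subtree lengths break to the lowest id
  nodes <- data.frame(id = 1:4, x = c(0, 0, -60, 60), y = 0,
                      z = c(0, 100, 220, 220),
                      is_boundary = c(TRUE, FALSE, TRUE, TRUE))
  vessels <- data.frame(id = 1:3, source = c(1, 2, 2), target = c(2, 3, 4),
                        diameter = c(12, 10, 10), length = c(100, 134, 134),
                        type = "DA", main_branch = FALSE)
  g3 <- split_main_branch(mvn_graph(nodes, vessels))
  expect_true(g3$vessels$main_branch[2])
  expect_false(g3$vessels$main_branch[3])
})

test_that("depth layers follow the slack rule and prefer the shallowest", {
  mk <- function(z1, z2) {
    n <- data.frame(id = 1:2, x = c(0, 100), y = 0, z = c(z1, z2),
                    is_boundary = TRUE)
    v <- data.frame(id = 1L, source = 1L, target = 2L, diameter = 5,
                    length = 120)
    assign_depth_layers(mvn_graph(n, v))$layer
  }
  expect_equal(mk(150, 230), 1L)   # 230 within 200 + 50 slack
  expect_equal(mk(150, 260), 2L)   # fails layer-1 slack, 150 >= 200 - 50
  expect_equal(mk(10, 20), 1L)

  # coverage: every vessel within [0, 5 x thickness] gets a layer
  net <- generate_lattice_mvn(generator_config(nx = 4, ny = 4, nz = 5, seed = 2))
  lay <- assign_depth_layers(net$graph)
  z <- range(net$graph$nodes$z)
  if (z[2] <= 5 * 200 + 50) expect_equal(attr(lay, "n_unassigned"), 0L)
})
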