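test_that("MSC classification is symmetric under global flow reversal and
           refuses non-degree-3 endpoints", {
  m <- make_msc_motif("2-2")
  fl <- solve_pressure_flow(m$graph, m$bc)
  expect_equal(classify_msc_type(m$graph, fl, m$msc), "2-2")
  # reverse all boundary pressures: convergent/divergent swap endpoints
  bc_rev <- boundary_conditions(m$bc$node, rev(m$bc$pressure),
                                inflow_hematocrit = m$bc$inflow_hematocrit)
  fl_rev <- solve_pressure_flow(m$graph, bc_rev)
  expect_equal(classify_msc_type(m$graph, fl_rev, m$msc), "2-2")
  # vessel at a degree-2 node is unclassifiable
  g <- chain_graph(c(5, 5, 5))
  bc <- boundary_conditions(c(1, 4), c(100, 0), unit = "Pa")
  flc <- solve_pressure_flow(g, bc)
  expect_true(is.na(classify_msc_type(g, flc, 2)))
})

test_that("generation maps have the expected per-type multiplicities", {
  m <- make_msc_motif("1-1")
  fl <- solve_pressure_flow(m$graph, m$bc)
  gens <- generations(m$graph, fl, m$msc)
  expect_equal(sum(gens$generation == -1), 1L)
  expect_equal(sum(gens$generation == 1), 1L)
  # chain of 11 vessels: one vessel per generation -5..5
  g <- chain_graph(rep(5, 11))
  bc <- boundary_conditions(c(1, 12), c(100, 0), unit = "Pa")
  flc <- solve_pressure_flow(g, bc)
  gens <- generations(g, flc, 6)
  expect_equal(sort(gens$generation), c(-5:-1, 1:5))
  expect_equal(gens$vessel[order(gens$generation)], c(1:5, 7:11))
})

test_that("grow_box solves the symmetric-expansion cubic", {
  side <- (nl_to_um3(0.2))^(1 / 3)
  expect_equal(side, 58.48035, tolerance = 1e-5)
  b0 <- rbind(c(0, 0, 0), rep(side, 3))
  grown <- grow_box(b0, nl_to_um3(0.4))
  expect_equal(unname(grown$bounds[2, 1] - grown$bounds[1, 1]),
               (4e5)^(1 / 3), tolerance = 1e-6)
  expect_equal(grow_box(b0, nl_to_um3(0.2))$delta, 0)
  expect_error(grow_box(b0, 1e3), "smaller")
  # oracle: independent bisection on random boxes
  draws <- with_seed_test(31, {
    replicate(200, list(b = sort(stats::runif(2, 10, 200)),
                        sides = stats::runif(3, 20, 150),
                        f = stats::runif(1, 1, 20)), simplify = FALSE)
  })
  for (d in draws) {
    b <- rbind(c(0, 0, 0), d$sides)
    target <- prod(d$sides) * d$f
    got <- grow_box(b, target)$delta
    # bisection oracle
    lo <- 0; hi <- max(target^(1 / 3), 1)
    while (prod(d$sides + hi) < target) hi <- hi * 2
    for (i in 1:80) {
      mid <- (lo + hi) / 2
      if (prod(d$sides + mid) < target) lo <- mid else hi <- mid
    }
    expect_equal(got, (lo + hi) / 2, tolerance = 1e-6)
  }
})

test_that("box vessel categories partition the box and capture bypasses", {
  m <- make_msc_motif("2-2")
  fl <- solve_pressure_flow(m$graph, m$bc)
  box <- msc_box(m$graph, m$msc, nl_to_um3(10))
  cats <- categorize_box_vessels(m$graph, fl, m$msc, box)
  expect_equal(anyDuplicated(cats$vessel), 0L)
  expect_setequal(unique(cats$category),
                  intersect(c("msc", "updown", "parallel", "distant"),
                            cats$category))
  # every in-box vessel is categorized exactly once (partition)
  inbox <- sapply(seq_len(nrow(m$graph$vessels)), function(i)
    mvnstroke:::clip_polyline_box(vessel_centerline(m$graph,
                                                    m$graph$vessels$id[i]),
                                  box)$length > 0)
  expect_equal(sort(cats$vessel), sort(m$graph$vessels$id[inbox]))
  # the b-side bypass vessels are parallel (they branch off generation 1/2)
  expect_true("parallel" %in% cats$category)
  # a box holding only the MSC and its direct neighbours has no distant
  small <- msc_box(m$graph, m$msc, nl_to_um3(0.2))
  cats_small <- categorize_box_vessels(m$graph, fl, m$msc, small)
  expect_false("distant" %in% cats_small$category)
})

test_that("polyline clipping yields exact lengths for straight segments", {
  box <- structure(list(bounds = rbind(c(0, 0, 0), c(50, 100, 100))),
                   class = "mvn_box")
  # vessel half inside the box
  cl <- rbind(c(0, 50, 50), c(100, 50, 50))
  expect_equal(mvnstroke:::clip_polyline_box(cl, box)$length, 50)
  cr <- mvnstroke:::clip_polyline_box(cl, box)$crossings
  expect_equal(length(cr), 1L)
  expect_lt(cr[1], 0)   # leaves the box at arc length 50
  expect_equal(abs(cr[1]), 50)
})

test_that("box inflow difference is zero for identical fields and matches
           the boundary inflow for a box covering the network", {
  sl <- shared_lattice()
  g <- sl$net$graph
  box_all <- structure(list(bounds = rbind(
    c(min(g$nodes$x), min(g$nodes$y), min(g$nodes$z)) - 100,
    c(max(g$nodes$x), max(g$nodes$y), max(g$nodes$z)) + 100)),
    class = "mvn_box")
  expect_equal(box_inflow_difference(sl$flow, sl$flow, g, box_all), 0)
  # a whole-network box sees exactly the boundary inflow
  inflow_box <- mvnstroke:::box_total_inflow(g, sl$flow, box_all)
  bnodes <- g$nodes$id[g$nodes$is_boundary]
  vi <- which(g$vessels$source %in% bnodes | g$vessels$target %in% bnodes)
  q <- sl$flow$q
  binflow <- sum(sapply(vi, function(v) {
    bn <- intersect(c(g$vessels$source[v], g$vessels$target[v]), bnodes)[1]
    into <- if (g$vessels$source[v] == bn) q[v] > 0 else q[v] < 0
    if (into) abs(q[v]) else 0
  }))
  expect_equal(inflow_box, binflow, tolerance = 1e-9)
})

test_that("box inflow accounting is invariant under rigid translation", {
  m <- make_msc_motif("2-2")
  fl <- solve_pressure_flow(m$graph, m$bc)
  box <- msc_box(m$graph, m$msc, nl_to_um3(1))
  v0 <- mvnstroke:::box_total_inflow(m$graph, fl, box)
  shift <- c(37, -12, 101)
  g2 <- m$graph
  g2$nodes$x <- g2$nodes$x + shift[1]
  g2$nodes$y <- g2$nodes$y + shift[2]
  g2$nodes$z <- g2$nodes$z + shift[3]
  g2$vessels$centerline <- lapply(g2$vessels$centerline, function(cl)
    sweep(cl, 2, shift, "+"))
  box2 <- structure(list(bounds = sweep(box$bounds, 2, shift, "+")),
                    class = "mvn_box")
  v1 <- mvnstroke:::box_total_inflow(g2, fl, box2)
  expect_equal(v1, v0, tolerance = 1e-9)
})

test_that("tissue grid partitions the volume and respects symmetry", {
  n <- data.frame(id = 1:4, x = c(0, 100, 0, 100), y = c(10, 10, 90, 90),
                  z = 50, is_boundary = TRUE)
  v <- data.frame(id = 1:2, source = c(1, 3), target = c(2, 4), diameter = 5,
                  length = 100)
  g <- mvn_graph(n, v)
  tg <- supplied_tissue_volume(g, cell = 4)
  expect_equal(sum(tg$volume), tg$n_cells * 4^3)
  expect_equal(unname(tg$volume["1"]), unname(tg$volume["2"]))
  # a single vessel supplies the whole grid
  g1 <- tube_graph()
  tg1 <- supplied_tissue_volume(g1, cell = 4)
  expect_equal(unname(tg1$volume["1"]), tg1$n_cells * 4^3)
})

test_that("grid nearest-vessel assignment matches brute force", {
  sl <- shared_lattice()
  g <- sl$net$graph
  disc <- discretize(g, spacing = 4)
  lo <- c(min(g$nodes$x), min(g$nodes$y), min(g$nodes$z))
  queries <- with_seed_test(17, cbind(stats::runif(200, lo[1], lo[1] + 150),
                                      stats::runif(200, lo[2], lo[2] + 150),
                                      stats::runif(200, lo[3], lo[3] + 150)))
  ord <- order(disc$vessel)
  pts <- disc$points[ord, ]
  vs <- disc$vessel[ord]
  nn <- mvnstroke:::.nn_index(pts, queries, cell_size = 20)
  for (k in seq_len(nrow(queries))) {
    dd <- colSums((t(pts) - queries[k, ])^2)
    expect_equal(dd[nn[k]], min(dd), tolerance = 1e-9)
  }
})
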