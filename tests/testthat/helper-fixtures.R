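# Shared fixtures and independent oracles for the test suite.

# straight two-node, one-vessel graph
tube_graph <- function(d = 10, len = 100) {
  mvn_graph(
    data.frame(id = 1:2, x = c(0, len), y = 0, z = 300,
               is_boundary = c(TRUE, TRUE)),
    data.frame(id = 1L, source = 1L, target = 2L, diameter = d, length = len))
}

# symmetric Y: one parent splitting into two identical daughters
y_graph <- function(d_parent = 8, d_daughter = 6) {
  nodes <- data.frame(id = 1:4,
                      x = c(0, 100, 200, 200), y = c(0, 0, 60, -60), z = 300,
                      is_boundary = c(TRUE, FALSE, TRUE, TRUE))
  vessels <- data.frame(id = 1:3, source = c(1, 2, 2), target = c(2, 3, 4),
                        diameter = c(d_parent, d_daughter, d_daughter),
                        length = c(100, 120, 120))
  mvn_graph(nodes, vessels)
}

# unbranched chain of n vessels with the given diameters
chain_graph <- function(diameters, len = 50, z0 = 0, boundary_first = TRUE) {
  n <- length(diameters)
  nodes <- data.frame(id = seq_len(n + 1), x = (seq_len(n + 1) - 1) * len,
                      y = 0, z = z0 + (seq_len(n + 1) - 1) * 0,
                      is_boundary = c(boundary_first, rep(FALSE, n - 1), TRUE))
  vessels <- data.frame(id = seq_len(n), source = seq_len(n),
                        target = seq_len(n) + 1, diameter = diameters,
                        length = len)
  mvn_graph(nodes, vessels)
}

# mirror-symmetric ladder: DA endpoint -> k three-segment rungs -> AV
# endpoint; the middle segment of every rung is equidistant from both sides.
ladder_fixture <- function(k = 3) {
  ys <- seq(-40 * (k - 1) / 2, 40 * (k - 1) / 2, length.out = k)
  nodes <- data.frame(id = 1:4, x = c(0, 100, 300, 400), y = 0, z = 300,
                      is_boundary = c(TRUE, FALSE, FALSE, TRUE))
  a <- 2L; b <- 3L
  vs <- list(data.frame(id = 1L, source = 1L, target = a, diameter = 8,
                        length = 100))
  vid <- 1L
  nid <- 4L
  for (j in seq_len(k)) {
    m1 <- nid + 1L; m2 <- nid + 2L; nid <- nid + 2L
    nodes <- rbind(nodes,
                   data.frame(id = c(m1, m2), x = c(160, 240), y = ys[j],
                              z = 300, is_boundary = FALSE))
    vs[[length(vs) + 1L]] <- data.frame(id = vid + 1L, source = a, target = m1,
                                        diameter = 5, length = 110)
    vs[[length(vs) + 1L]] <- data.frame(id = vid + 2L, source = m1, target = m2,
                                        diameter = 5, length = 85)
    vs[[length(vs) + 1L]] <- data.frame(id = vid + 3L, source = m2, target = b,
                                        diameter = 5, length = 110)
    vid <- vid + 3L
  }
  vs[[length(vs) + 1L]] <- data.frame(id = vid + 1L, source = b, target = 4L,
                                      diameter = 8, length = 100)
  mvn_graph(nodes, do.call(rbind, vs))
}

# independent transcription of the empirical rheology laws (kept separate
# from the package implementation on purpose)
oracle_mu_rel <- function(d, h) {
  eta45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  tt <- 1 / (1 + 1e-11 * d^12)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + tt) + tt
  1 + (eta45 - 1) * ((1 - h)^cc - 1) / ((1 - 0.45)^cc - 1)
}

oracle_fqe <- function(fqb, dp, d1, d2, h) {
  x0 <- 0.964 * (1 - h) / dp
  a <- -13.29 * ((d1^2 / d2^2 - 1) / (d1^2 / d2^2 + 1)) * (1 - h) / dp
  b <- 1 + 6.98 * (1 - h) / dp
  if (fqb <= x0) return(0)
  if (fqb >= 1 - x0) return(1)
  xr <- (fqb - x0) / (1 - 2 * x0)
  stats::plogis(a + b * log(xr / (1 - xr)))
}

# exhaustive DFS enumeration of directed paths between node sets on a DAG
# given as a data.frame(from, to, len); independent of the package DP
oracle_enumerate_paths <- function(edges, sources, sinks) {
  out_edges <- split(seq_len(nrow(edges)), edges$from)
  paths <- list()
  walk <- function(node, len, visited) {
    if (node %in% sinks) paths[[length(paths) + 1L]] <<- len
    for (ei in out_edges[[as.character(node)]]) {
      walk(edges$to[ei], len + edges$len[ei], visited)
    }
  }
  for (s in sources) walk(s, 0, integer(0))
  unlist(paths) %||% numeric(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random DAG on n nodes by orienting random edges along a random node order
random_dag <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  ord <- sample(n_nodes)
  from <- integer(0); to <- integer(0)
  while (length(from) < n_edges) {
    u <- sample(n_nodes, 1); v <- sample(n_nodes, 1)
    if (u == v) next
    if (which(ord == u) > which(ord == v)) { tmp <- u; u <- v; v <- tmp }
    from <- c(from, u); to <- c(to, v)
  }
  data.frame(from = from, to = to, len = stats::runif(n_edges, 10, 100))
}

# small solved lattice shared by several tests (cached per session)
shared_lattice <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- generate_lattice_mvn(generator_config(nx = 6, ny = 6, nz = 6,
                                                   seed = 7))
      fl <- solve_pressure_flow(net$graph, net$bc)
      cache <<- list(net = net, flow = fl)
    }
    cache
  }
})

# evaluate code under a seed without touching the suite RNG stream
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# wraps a raw DAG edge table in a flow_dag-like object for count_paths
dag_from_edges <- function(edges, sources, sinks) {
  ig <- igraph::graph_from_edgelist(cbind(as.character(edges$from),
                                          as.character(edges$to)),
                                    directed = TRUE)
  ord <- as.integer(names(igraph::topo_sort(ig, mode = "out")))
  structure(list(edges = data.frame(vessel = seq_len(nrow(edges)),
                                    from = edges$from, to = edges$to),
                 da_endpoints = sources, av_endpoints = sinks,
                 order = ord, q_eps = 0), class = "flow_dag")
}

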