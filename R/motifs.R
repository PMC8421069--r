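#' Minimal microstroke motif networks
#'
#' Small (<= 40 vessel) networks whose central capillary realizes a
#' requested topological configuration under its solved baseline flow:
#' `"2-2"` (convergent bifurcation upstream, divergent downstream),
#' `"2-1"`, `"1-2"`, or `"1-1"`. Each motif includes bypass paths so that
#' occluding the central capillary neither disconnects the bed nor
#' symmetrizes it: after occlusion of a `2-2` motif exactly one
#' generation -1 and one generation +1 vessel reverses flow while the
#' others keep their direction.
#'
#' @param msc_type one of `"2-2"`, `"2-1"`, `"1-2"`, `"1-1"`.
#' @param p_in,p_out boundary pressures (mmHg) at the feeding and draining
#'   node, defaults 40 and 15.
#' @param inflow_hematocrit inflow discharge hematocrit, default 0.3.
#' @return list with `graph`, `bc`, and `msc` (the central vessel id).
#' @export
make_msc_motif <- function(msc_type = c("2-2", "2-1", "1-2", "1-1"),
                           p_in = 40, p_out = 15, inflow_hematocrit = 0.3) {
  msc_type <- match.arg(msc_type)
  b <- motif_builder()
  S <- b$node(0, 0, 300, boundary = TRUE)
  n1 <- b$node(60, 0, 300)
  n2 <- b$node(420, 0, 300)
  T <- b$node(480, 0, 300, boundary = TRUE)
  U <- b$node(180, 0, 300)
  V <- b$node(240, 0, 300)
  b$vessel(S, n1, d = 8)               # feed
  b$vessel(n2, T, d = 8)               # drain
  msc <- b$vessel(U, V, d = 5)         # central capillary

  if (startsWith(msc_type, "2")) {
    # convergent upstream: two distinct feeders a, b into U; the b-side
    # bypass is long/thin so post-occlusion flow runs a -> U -> b (one
    # generation -1 reversal)
    a <- b$node(120, 50, 300)
    bb <- b$node(120, -50, 300)
    b$vessel(n1, a, d = 5.5)
    b$vessel(n1, bb, d = 5.5)
    b$vessel(a, U, d = 5)              # generation -1 (stays)
    b$vessel(bb, U, d = 5)             # generation -1 (reverses)
    m2 <- b$node(240, -110, 300)
    b$vessel(bb, m2, d = 4.2, len_factor = 2.0)
    b$vessel(m2, n2, d = 4.2, len_factor = 2.0)
  } else {
    # divergent upstream: one feeder plus a side outflow from U
    b$vessel(n1, U, d = 5.5)           # generation -1
    w <- b$node(180, 70, 300)
    b$vessel(U, w, d = 4.6)
    b$vessel(w, n2, d = 4.6, len_factor = 1.6)
  }

  if (endsWith(msc_type, "2")) {
    # divergent downstream: two drains c, d out of V; the c-side bypass is
    # short/wide so post-occlusion flow runs c -> V -> d (one generation +1
    # reversal)
    cc <- b$node(300, 50, 300)
    dd <- b$node(300, -50, 300)
    b$vessel(V, cc, d = 5)             # generation +1 (reverses)
    b$vessel(V, dd, d = 5)             # generation +1 (stays)
    b$vessel(cc, n2, d = 5.5)
    b$vessel(dd, n2, d = 5.5)
    m1 <- b$node(180, 110, 300)
    b$vessel(n1, m1, d = 5.2, len_factor = 1.2)
    b$vessel(m1, cc, d = 5.2, len_factor = 1.2)
  } else {
    # convergent downstream: a side inflow into V plus one drain
    b$vessel(V, n2, d = 5.5)           # generation +1
    x <- b$node(240, 70, 300)
    b$vessel(n1, x, d = 4.6, len_factor = 1.6)
    b$vessel(x, V, d = 4.6)
  }

  # a far bypass keeps the bed perfused whatever the occlusion does
  f1 <- b$node(180, -160, 300)
  f2 <- b$node(300, -160, 300)
  b$vessel(n1, f1, d = 5, len_factor = 1.3)
  b$vessel(f1, f2, d = 5, len_factor = 1.3)
  b$vessel(f2, n2, d = 5, len_factor = 1.3)

  g <- b$graph()
  bc <- boundary_conditions(c(S, T), c(p_in, p_out), unit = "mmHg",
                            inflow_hematocrit = inflow_hematocrit)
  list(graph = g, bc = bc, msc = msc)
}

#' Degenerate shared-generation-2 fixture
#'
#' A `2-2` configuration in which both generation -1 vessels originate from
#' the same generation -2 node and both generation +1 vessels drain into the
#' same generation +2 node. Occluding the central capillary then leaves both
#' endpoint nodes without any pressure difference across their remaining
#' vessels, so flow in all four generation ±1 vessels ceases instead of
#' reversing — the rare cessation outcome.
#'
#' @inheritParams make_msc_motif
#' @return list with `graph`, `bc`, and `msc`.
#' @export
special_gen1_fixture <- function(p_in = 40, p_out = 15,
                                 inflow_hematocrit = 0.3) {
  b <- motif_builder()
  S <- b$node(0, 0, 300, boundary = TRUE)
  W <- b$node(100, 0, 300)    # shared generation -2 node
  U <- b$node(180, 0, 300)
  V <- b$node(260, 0, 300)
  X <- b$node(340, 0, 300)    # shared generation +2 node
  T <- b$node(440, 0, 300, boundary = TRUE)
  b$vessel(S, W, d = 7)
  msc <- local({
    # twin generation -1 vessels W -> U (slightly different diameters)
    b$vessel(W, U, d = 5.2, len_factor = 1.15)
    b$vessel(W, U, d = 4.8, len_factor = 1.15)
    m <- b$vessel(U, V, d = 5)
    b$vessel(V, X, d = 5.2, len_factor = 1.15)
    b$vessel(V, X, d = 4.8, len_factor = 1.15)
    m
  })
  b$vessel(X, T, d = 7)
  # bypass so the network stays perfused after occlusion
  f1 <- b$node(180, -120, 300)
  f2 <- b$node(260, -120, 300)
  b$vessel(W, f1, d = 5)
  b$vessel(f1, f2, d = 5)
  b$vessel(f2, X, d = 5)
  g <- b$graph()
  bc <- boundary_conditions(c(S, T), c(p_in, p_out), unit = "mmHg",
                            inflow_hematocrit = inflow_hematocrit)
  list(graph = g, bc = bc, msc = msc)
}

# incremental builder for small hand-made networks; default vessel length is
# 1.05 x chord, scaled by len_factor, with a matching curved centerline
motif_builder <- function() {
  nodes <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), is_boundary = logical())
  vessels <- data.frame(id = integer(), source = integer(), target = integer(),
                        diameter = numeric(), length = numeric(),
                        type = character(), main_branch = logical(),
                        stringsAsFactors = FALSE)
  cls <- list()
  node <- function(x, y, z, boundary = FALSE) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, x, y, z, boundary)
    id
  }
  vessel <- function(src, tgt, d, len_factor = 1.05, type = "C") {
    id <- nrow(vessels) + 1L
    p0 <- as.numeric(nodes[src, c("x", "y", "z")])
    p1 <- as.numeric(nodes[tgt, c("x", "y", "z")])
    chord <- sqrt(sum((p1 - p0)^2))
    len <- chord * len_factor
    vessels[id, ] <<- list(id, src, tgt, d, len, type, FALSE)
    cls[[id]] <<- make_centerline(p0, p1, len)
    id
  }
  graph <- function() {
    vessels$centerline <- cls
    mvn_graph(nodes, vessels)
  }
  list(node = node, vessel = vessel, graph = graph)
}
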