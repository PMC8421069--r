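#' Configuration of the synthetic network generator
#'
#' Describes a jittered, diluted 3-D capillary lattice with penetrating
#' arteriole (DA) and venule (AV) trees. Defaults emulate the statistics of
#' cortical capillary beds: diameters roughly 4-10 um, tortuous lengths
#' roughly 40-80 um, interior bifurcations of degree 3, and a wide, skewed
#' flow distribution with a median near 2 um^3/ms under the default
#' boundary pressures.
#'
#' @param nx,ny,nz lattice dimensions (nodes per axis), default 10.
#' @param spacing lattice node spacing (um), default 55.
#' @param jitter positional jitter as a fraction of `spacing`, default 0.18.
#' @param cap_diameter_mean,cap_diameter_cv lognormal capillary diameter
#'   distribution (um), default mean 4, cv 0.25.
#' @param cap_length_mean,cap_length_cv lognormal capillary length
#'   distribution (um), default mean 62, cv 0.22; lengths are floored at
#'   1.005 times the chord (tortuosity >= 1).
#' @param mean_degree target mean degree of interior lattice nodes,
#'   default 3.
#' @param n_da,n_av number of penetrating arteriole / venule trees,
#'   default 2 each.
#' @param tree_depth number of main-branch trunk segments per tree,
#'   default 4.
#' @param p_da,p_av boundary pressures at DA / AV roots (mmHg), default
#'   60 and 15; capillary boundary stubs are interpolated between them by
#'   normalized topological distance.
#' @param boundary_fraction fraction of lateral-face lattice nodes that
#'   receive a pressure boundary stub, default 0.25.
#' @param inflow_hematocrit inflow discharge hematocrit, default 0.3.
#' @param seed integer seed; fully determines the generated network.
#' @return a list of class `mvn_gen_config`.
#' @export
generator_config <- function(nx = 10, ny = 10, nz = 10, spacing = 55,
                             jitter = 0.18,
                             cap_diameter_mean = 4, cap_diameter_cv = 0.25,
                             cap_length_mean = 62, cap_length_cv = 0.22,
                             mean_degree = 3, n_da = 2, n_av = 2,
                             tree_depth = 4, p_da = 60, p_av = 15,
                             boundary_fraction = 0.25,
                             inflow_hematocrit = 0.3, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(nx >= 3, ny >= 3, nz >= 3, spacing > 0,
            cap_diameter_mean > 0, cap_diameter_cv > 0,
            cap_length_mean > 0, cap_length_cv > 0,
            mean_degree > 2, n_da >= 1, n_av >= 1, tree_depth >= 1,
            inflow_hematocrit >= 0, inflow_hematocrit < 1)
  class(cfg) <- "mvn_gen_config"
  cfg
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# two-segment polyline from p0 to p1 with total length target_len (>= chord)
make_centerline <- function(p0, p1, target_len) {
  chord <- sqrt(sum((p1 - p0)^2))
  if (target_len <= chord * (1 + 1e-6)) return(rbind(p0, p1))
  h <- sqrt((target_len / 2)^2 - (chord / 2)^2)
  mid <- (p0 + p1) / 2
  d <- (p1 - p0) / chord
  # any unit vector perpendicular to d
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- ref - sum(ref * d) * d
  perp <- perp / sqrt(sum(perp^2))
  rbind(p0, mid + h * perp, p1)
}

#' Generate a synthetic microvascular network
#'
#' Builds a jittered capillary lattice (random spanning tree plus random
#' extra edges up to the target mean degree, so connectivity is guaranteed
#' and interior bifurcations have degree about 3), attaches `n_da` DA and
#' `n_av` AV penetrating trees with tapered main branches and offshoots,
#' adds pressure boundary stubs on the lateral faces, and assigns boundary
#' pressures: DA roots at `p_da`, AV roots at `p_av`, capillary stubs
#' linearly interpolated by normalized topological distance between the
#' root sets. The same seed always yields an identical network.
#'
#' @param cfg a [generator_config()].
#' @return list with elements `graph` (an [mvn_graph()]) and `bc`
#'   (a [boundary_conditions()]).
#' @export
generate_lattice_mvn <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "mvn_gen_config"))
  with_seed(cfg$seed, build_lattice_mvn(cfg))
}

build_lattice_mvn <- function(cfg) {
  nx <- cfg$nx; ny <- cfg$ny; nz <- cfg$nz; s <- cfg$spacing
  idx <- function(i, j, k) (k - 1L) * nx * ny + (j - 1L) * nx + i
  grid <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  n_lat <- nrow(grid)
  bed_top <- 100  # um below the cortical surface
  pos <- cbind(x = (grid$i - 1) * s, y = (grid$j - 1) * s,
               z = bed_top + (grid$k - 1) * s)
  pos <- pos + matrix(stats::runif(3 * n_lat, -cfg$jitter * s, cfg$jitter * s),
                      ncol = 3)
  # candidate 6-neighbour edges
  cand <- rbind(
    if (nx > 1) cbind(idx(grid$i[grid$i < nx], grid$j[grid$i < nx], grid$k[grid$i < nx]),
                      idx(grid$i[grid$i < nx] + 1L, grid$j[grid$i < nx], grid$k[grid$i < nx])),
    if (ny > 1) cbind(idx(grid$i[grid$j < ny], grid$j[grid$j < ny], grid$k[grid$j < ny]),
                      idx(grid$i[grid$j < ny], grid$j[grid$j < ny] + 1L, grid$k[grid$j < ny])),
    if (nz > 1) cbind(idx(grid$i[grid$k < nz], grid$j[grid$k < nz], grid$k[grid$k < nz]),
                      idx(grid$i[grid$k < nz], grid$j[grid$k < nz], grid$k[grid$k < nz] + 1L)))
  # random spanning tree, then random extra edges to the target mean degree
  ig <- igraph::graph_from_edgelist(cbind(as.character(cand[, 1]),
                                          as.character(cand[, 2])),
                                    directed = FALSE)
  igraph::E(ig)$weight <- stats::runif(nrow(cand))
  igraph::E(ig)$cand_row <- seq_len(nrow(cand))
  mst <- igraph::mst(ig)
  keep <- sort(igraph::E(mst)$cand_row)
  n_target <- ceiling(cfg$mean_degree * n_lat / 2)
  extra_pool <- sample(setdiff(seq_len(nrow(cand)), keep))
  # grow toward degree-3 interior bifurcations: extra edges only attach to
  # nodes still below degree 3, then (if the budget remains) below degree 4
  deg <- tabulate(cand[keep, ], nbins = n_lat)
  for (cap in c(3L, 4L)) {
    for (r in extra_pool) {
      if (length(keep) >= n_target) break
      u <- cand[r, 1]; v <- cand[r, 2]
      if (deg[u] < cap && deg[v] < cap) {
        keep <- c(keep, r)
        deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
      }
    }
    extra_pool <- setdiff(extra_pool, keep)
  }
  edges <- cand[sort(keep), , drop = FALSE]

  nodes <- data.frame(id = seq_len(n_lat), x = pos[, 1], y = pos[, 2],
                      z = pos[, 3], is_boundary = FALSE)
  ne <- nrow(edges)
  vessels <- data.frame(id = seq_len(ne), source = edges[, 1],
                        target = edges[, 2],
                        diameter = rlnorm_mean_cv(ne, cfg$cap_diameter_mean,
                                                  cfg$cap_diameter_cv),
                        length = NA_real_, type = "C", main_branch = FALSE,
                        stringsAsFactors = FALSE)

  next_node <- n_lat
  next_vessel <- ne
  add_node <- function(x, y, z, boundary = FALSE) {
    next_node <<- next_node + 1L
    nodes[nrow(nodes) + 1L, ] <<- list(next_node, x, y, z, boundary)
    next_node
  }
  add_vessel <- function(src, tgt, d, type, main = FALSE, len = NA_real_) {
    next_vessel <<- next_vessel + 1L
    vessels[nrow(vessels) + 1L, ] <<- list(next_vessel, src, tgt, d, len,
                                           type, main)
    next_vessel
  }

  # penetrating trees: tapered trunk descending from the surface into the
  # bed, offshoots connecting trunk nodes to nearby lattice nodes
  tree_spec <- data.frame(
    side = c(rep("DA", cfg$n_da), rep("AV", cfg$n_av)),
    stringsAsFactors = FALSE)
  # spread roots over the x-y extent
  nt <- nrow(tree_spec)
  root_xy <- cbind(x = ((seq_len(nt) - 0.5) / nt) * (nx - 1) * s,
                   y = stats::runif(nt, 0.2, 0.8) * (ny - 1) * s)
  roots <- integer(nt)
  for (t in seq_len(nt)) {
    side <- tree_spec$side[t]
    d_top <- if (side == "DA") 14 else 17
    d_bot <- if (side == "DA") 8 else 10
    depth_reach <- bed_top + (cfg$tree_depth - 1) * s
    root <- add_node(root_xy[t, 1], root_xy[t, 2], 0, boundary = TRUE)
    roots[t] <- root
    prev <- root
    trunk_nodes <- integer(cfg$tree_depth)
    for (lvl in seq_len(cfg$tree_depth)) {
      zz <- lvl / cfg$tree_depth * depth_reach
      nd <- add_node(root_xy[t, 1] + stats::runif(1, -0.1 * s, 0.1 * s),
                     root_xy[t, 2] + stats::runif(1, -0.1 * s, 0.1 * s), zz)
      dtrunk <- d_top + (d_bot - d_top) * (lvl - 1) / max(cfg$tree_depth - 1, 1)
      add_vessel(prev, nd, dtrunk, side, main = TRUE)
      trunk_nodes[lvl] <- nd
      prev <- nd
    }
    # offshoots from each below-surface trunk node to the nearest lattice
    # nodes (diameter just above the 6 um type threshold)
    for (nd in trunk_nodes) {
      p <- c(nodes$x[nd], nodes$y[nd], nodes$z[nd])
      d2 <- (pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2 + (pos[, 3] - p[3])^2
      near <- order(d2)[1:2]
      for (ln in near) {
        add_vessel(nd, ln, stats::runif(1, 6.2, 7.2), side, main = FALSE)
      }
    }
  }

  # boundary stubs on the four lateral faces
  on_face <- grid$i == 1L | grid$i == nx | grid$j == 1L | grid$j == ny
  face_nodes <- which(on_face)
  n_stub <- max(2L, round(cfg$boundary_fraction * length(face_nodes)))
  stub_nodes <- sample(face_nodes, n_stub)
  for (ln in stub_nodes) {
    dir <- c(if (grid$i[ln] == 1L) -1 else if (grid$i[ln] == nx) 1 else 0,
             if (grid$j[ln] == 1L) -1 else if (grid$j[ln] == ny) 1 else 0, 0)
    dir <- dir / sqrt(sum(dir^2))
    bn <- add_node(nodes$x[ln] + 30 * dir[1], nodes$y[ln] + 30 * dir[2],
                   nodes$z[ln], boundary = TRUE)
    add_vessel(ln, bn, stats::runif(1, 4.2, 5.8), "C")
  }

  # lengths and centerlines
  p1 <- as.matrix(nodes[match(vessels$source, nodes$id), c("x", "y", "z")])
  p2 <- as.matrix(nodes[match(vessels$target, nodes$id), c("x", "y", "z")])
  chord <- sqrt(rowSums((p1 - p2)^2))
  is_cap <- vessels$type == "C"
  len <- chord * 1.02
  len[is_cap] <- pmax(rlnorm_mean_cv(sum(is_cap), cfg$cap_length_mean,
                                     cfg$cap_length_cv), chord[is_cap] * 1.005)
  vessels$length <- len
  cl <- vector("list", nrow(vessels))
  for (i in seq_len(nrow(vessels))) {
    cl[[i]] <- make_centerline(p1[i, ], p2[i, ], len[i])
  }
  vessels$centerline <- cl

  g <- mvn_graph(nodes, vessels)

  # boundary pressures: roots fixed, stubs interpolated by topological
  # distance between the DA-root and AV-root sets
  ig2 <- as_igraph(g)
  da_roots <- roots[tree_spec$side == "DA"]
  av_roots <- roots[tree_spec$side == "AV"]
  bnodes <- g$nodes$id[g$nodes$is_boundary]
  d_da <- suppressWarnings(igraph::distances(ig2, v = as.character(bnodes),
                                             to = as.character(da_roots)))
  d_av <- suppressWarnings(igraph::distances(ig2, v = as.character(bnodes),
                                             to = as.character(av_roots)))
  ddmin <- apply(d_da, 1, min); damin <- apply(d_av, 1, min)
  w <- damin / pmax(ddmin + damin, 1)
  p_mmHg <- cfg$p_av + w * (cfg$p_da - cfg$p_av)
  p_mmHg[match(da_roots, bnodes)] <- cfg$p_da
  p_mmHg[match(av_roots, bnodes)] <- cfg$p_av
  bc <- boundary_conditions(bnodes, p_mmHg, unit = "mmHg",
                            inflow_hematocrit = cfg$inflow_hematocrit)

  comp <- igraph::components(ig2)
  if (comp$no != 1L) {
    stop("generated network is disconnected (", comp$no,
         " components); adjust the generator configuration")
  }
  list(graph = g, bc = bc, config = cfg)
}
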