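#' Classify the topological configuration at a capillary
#'
#' Orients the vessel by its baseline flow and counts the inflows at the
#' upstream endpoint and the outflows at the downstream endpoint: a
#' convergent bifurcation upstream with a divergent one downstream gives
#' `"2-2"` (the worst-case microstroke configuration), a divergent upstream
#' with a convergent downstream gives `"1-1"`, and so on. Classification
#' requires both endpoints to have degree 3 and all five local flows to be
#' known, i.e. above `q_tol`; otherwise `NA` is returned.
#'
#' @param g an [mvn_graph()].
#' @param flow an `mvn_flow` (or time-averaged field) on `g`.
#' @param vessel_id vessel to classify.
#' @param q_tol flow magnitude below which a direction is considered
#'   unknown (um^3/ms), default 1e-8.
#' @param inc precomputed incidence structure (internal; speeds up
#'   classifying many vessels on the same graph).
#' @return one of `"2-2"`, `"2-1"`, `"1-2"`, `"1-1"`, or `NA_character_`.
#' @export
classify_msc_type <- function(g, flow, vessel_id, q_tol = 1e-8, inc = NULL) {
  vi <- match(vessel_id, g$vessels$id)
  if (is.na(vi)) stop("unknown vessel id ", vessel_id)
  q <- flow_of(flow, g)
  if (abs(q[vi]) <= q_tol) return(NA_character_)
  up_node <- if (q[vi] >= 0) g$vessels$source[vi] else g$vessels$target[vi]
  dn_node <- if (q[vi] >= 0) g$vessels$target[vi] else g$vessels$source[vi]
  if (is.null(inc)) inc <- incidence_list(g)
  up_inc <- setdiff(inc[[as.character(up_node)]], vi)
  dn_inc <- setdiff(inc[[as.character(dn_node)]], vi)
  if (length(up_inc) != 2L || length(dn_inc) != 2L) return(NA_character_)
  if (any(abs(q[c(up_inc, dn_inc)]) <= q_tol)) return(NA_character_)
  flows_into <- function(vj, node) {
    (q[vj] >= 0 & g$vessels$target[vj] == node) |
      (q[vj] < 0 & g$vessels$source[vj] == node)
  }
  n_in <- sum(vapply(up_inc, flows_into, logical(1), node = up_node))
  n_out <- sum(!vapply(dn_inc, flows_into, logical(1), node = dn_node))
  paste0(n_in, "-", n_out)
}

#' Signed per-vessel flow of a steady or time-averaged field
#'
#' Uniform accessor used throughout the analyses: returns `q` for a steady
#' `mvn_flow` and `mean_q` for a time-averaged field, in vessel-table order.
#'
#' @param flow an `mvn_flow` or `mvn_tavg`.
#' @param g the [mvn_graph()] the field belongs to.
#' @return numeric vector of signed flows (um^3/ms).
#' @export
flow_of <- function(flow, g) {
  q <- if (!is.null(flow$q)) flow$q else flow$mean_q
  stopifnot(length(q) == nrow(g$vessels))
  q
}

#' Signed generation map around a microstroke capillary
#'
#' Generation -1 vessels carry baseline flow into the MSC's upstream
#' endpoint; generation -(k+1) vessels carry flow into the upstream
#' endpoints of generation -k vessels, and mirrored downstream. A vessel
#' reachable at several depths keeps its first (smallest |generation|)
#' assignment; on an exact upstream/downstream tie the upstream label wins.
#'
#' @inheritParams classify_msc_type
#' @param msc MSC vessel id.
#' @param depth maximum generation, default 5.
#' @return data.frame `vessel`, `generation` (negative upstream, positive
#'   downstream).
#' @export
generations <- function(g, flow, msc, depth = 5, q_tol = 1e-8) {
  vi <- match(msc, g$vessels$id)
  q <- flow_of(flow, g)
  inc <- incidence_list(g)
  up_node_of <- function(vj) if (q[vj] >= 0) g$vessels$source[vj] else g$vessels$target[vj]
  dn_node_of <- function(vj) if (q[vj] >= 0) g$vessels$target[vj] else g$vessels$source[vj]
  gen <- stats::setNames(integer(0), character(0))
  assigned <- vi
  frontier_up <- vi
  frontier_dn <- vi
  for (k in seq_len(depth)) {
    # upstream: inflow vessels at the upstream endpoints of the frontier
    new_up <- integer(0)
    for (vj in frontier_up) {
      node <- up_node_of(vj)
      for (vk in setdiff(inc[[as.character(node)]], c(assigned))) {
        if (abs(q[vk]) <= q_tol) next
        if (dn_node_of(vk) == node) new_up <- c(new_up, vk)
      }
    }
    new_up <- unique(new_up)
    new_dn <- integer(0)
    for (vj in frontier_dn) {
      node <- dn_node_of(vj)
      for (vk in setdiff(inc[[as.character(node)]], c(assigned, new_up))) {
        if (abs(q[vk]) <= q_tol) next
        if (up_node_of(vk) == node) new_dn <- c(new_dn, vk)
      }
    }
    new_dn <- unique(new_dn)
    for (vk in new_up) gen[as.character(vk)] <- -k
    for (vk in new_dn) gen[as.character(vk)] <- k
    assigned <- c(assigned, new_up, new_dn)
    frontier_up <- new_up
    frontier_dn <- new_dn
    if (!length(new_up) && !length(new_dn)) break
  }
  data.frame(vessel = g$vessels$id[as.integer(names(gen))],
             generation = unname(gen))
}

#' Axis-aligned analysis box around a microstroke capillary
#'
#' The initial box is the axis-aligned bounding box of the MSC centerline
#' grown symmetrically to the target volume: all three side lengths are
#' increased by the same distance `delta` solving
#' `(a + delta)(b + delta)(c + delta) = V` (monotone root find).
#'
#' @param bounds 2 x 3 matrix: row 1 lower, row 2 upper corner (um).
#' @param target_volume target box volume (um^3), >= the initial volume.
#' @param tol relative tolerance of the root find, default 1e-6.
#' @return list of class `mvn_box`: `bounds`, `volume`, `volume_factor`
#'   (volume / 0.2 nl).
#' @export
grow_box <- function(bounds, target_volume, tol = 1e-6) {
  stopifnot(is.matrix(bounds), nrow(bounds) == 2, ncol(bounds) == 3)
  side <- bounds[2, ] - bounds[1, ]
  stopifnot(all(side >= 0))
  v0 <- prod(side)
  if (target_volume < v0 * (1 - 1e-12)) {
    stop("target volume smaller than the initial box volume")
  }
  f <- function(d) prod(side + d) - target_volume
  if (target_volume <= v0) {
    delta <- 0
  } else {
    hi <- max(target_volume^(1 / 3), 1)
    while (f(hi) < 0) hi <- hi * 2
    delta <- stats::uniroot(f, c(0, hi), tol = tol * 1e-4 * max(hi, 1))$root
  }
  new_bounds <- rbind(bounds[1, ] - delta / 2, bounds[2, ] + delta / 2)
  structure(list(bounds = new_bounds, volume = prod(new_bounds[2, ] - new_bounds[1, ]),
                 volume_factor = prod(new_bounds[2, ] - new_bounds[1, ]) / nl_to_um3(0.2),
                 delta = delta),
            class = "mvn_box")
}

#' @rdname grow_box
#' @param g an [mvn_graph()].
#' @param msc MSC vessel id.
#' @export
msc_box <- function(g, msc, target_volume) {
  cl <- vessel_centerline(g, msc)
  bounds <- rbind(apply(cl, 2, min), apply(cl, 2, max))
  grow_box(bounds, target_volume)
}

in_box <- function(p, box) {
  b <- box$bounds
  p[, 1] >= b[1, 1] & p[, 1] <= b[2, 1] &
    p[, 2] >= b[1, 2] & p[, 2] <= b[2, 2] &
    p[, 3] >= b[1, 3] & p[, 3] <= b[2, 3]
}

# clip a polyline to an axis-aligned box; returns clipped length and the
# ordered boundary crossings (arc position and direction: +1 entering,
# -1 leaving)
clip_polyline_box <- function(cl, box) {
  lo <- box$bounds[1, ]; hi <- box$bounds[2, ]
  total <- 0
  crossings <- numeric(0)
  arc <- 0
  for (s in seq_len(nrow(cl) - 1)) {
    p0 <- cl[s, ]; p1 <- cl[s + 1, ]
    d <- p1 - p0
    seg_len <- sqrt(sum(d^2))
    if (seg_len == 0) next
    t0 <- 0; t1 <- 1
    ok <- TRUE
    for (ax in 1:3) {
      if (d[ax] == 0) {
        if (p0[ax] < lo[ax] || p0[ax] > hi[ax]) { ok <- FALSE; break }
      } else {
        ta <- (lo[ax] - p0[ax]) / d[ax]
        tb <- (hi[ax] - p0[ax]) / d[ax]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    if (ok && t1 > t0) {
      total <- total + (t1 - t0) * seg_len
      if (t0 > 0) crossings <- c(crossings, +(arc + t0 * seg_len))
      if (t1 < 1) crossings <- c(crossings, -(arc + t1 * seg_len))
    }
    arc <- arc + seg_len
  }
  list(length = total, crossings = crossings, total_arc = arc)
}

#' Categorize vessels inside an analysis box
#'
#' Partition of the vessels whose centerline intersects the box into
#' `updown` (generations ±1..±`depth` of the MSC), `parallel` (vessels
#' branching off or into a generation-1/2 vessel, followed up to three
#' further segments), and `distant` (the rest). Categories are disjoint and
#' exhaustive within the box.
#'
#' @inheritParams generations
#' @param box an `mvn_box` from [grow_box()]/[msc_box()].
#' @param parallel_follow number of segments each parallel vessel is
#'   followed beyond the branch-off, default 3.
#' @return data.frame `vessel`, `category` (`"msc"`, `"updown"`,
#'   `"parallel"`, `"distant"`).
#' @export
categorize_box_vessels <- function(g, flow, msc, box, depth = 5,
                                   parallel_follow = 3, q_tol = 1e-8) {
  gens <- generations(g, flow, msc, depth = depth, q_tol = q_tol)
  inbox <- vapply(seq_len(nrow(g$vessels)), function(i) {
    clip_polyline_box(vessel_centerline(g, g$vessels$id[i]), box)$length > 0
  }, logical(1))
  ids_in <- g$vessels$id[inbox]
  updown <- intersect(gens$vessel, ids_in)
  # parallel: neighbours of generation 1/2 vessels plus three follow segments
  g12 <- gens$vessel[abs(gens$generation) <= 2]
  inc <- incidence_list(g)
  excluded <- c(msc, gens$vessel)
  seed_par <- integer(0)
  for (vid in g12) {
    vi <- match(vid, g$vessels$id)
    for (node in c(g$vessels$source[vi], g$vessels$target[vi])) {
      nb <- g$vessels$id[inc[[as.character(node)]]]
      seed_par <- c(seed_par, setdiff(nb, excluded))
    }
  }
  par_set <- unique(seed_par)
  frontier <- par_set
  for (k in seq_len(parallel_follow)) {
    nxt <- integer(0)
    for (vid in frontier) {
      vi <- match(vid, g$vessels$id)
      for (node in c(g$vessels$source[vi], g$vessels$target[vi])) {
        nb <- g$vessels$id[inc[[as.character(node)]]]
        nxt <- c(nxt, setdiff(nb, c(excluded, par_set)))
      }
    }
    nxt <- unique(nxt)
    par_set <- c(par_set, nxt)
    frontier <- nxt
    if (!length(frontier)) break
  }
  parallel <- intersect(par_set, ids_in)
  category <- rep("distant", length(ids_in))
  category[ids_in %in% parallel] <- "parallel"
  category[ids_in %in% updown] <- "updown"
  category[ids_in == msc] <- "msc"
  data.frame(vessel = ids_in, category = category, stringsAsFactors = FALSE)
}

#' Relative change of total inflow into an analysis box
#'
#' Inflow vessels are found independently for the baseline and the
#' perturbed field (flow reversals can change the set): every crossing of a
#' vessel centerline through the box boundary with flow directed inward
#' contributes that vessel's |q|. Returns `(in_stroke - in_base)/in_base`.
#'
#' @param base,stroke flow fields on `g`.
#' @param g an [mvn_graph()].
#' @param box an `mvn_box`.
#' @return relative inflow difference (fraction); `NA` if the baseline
#'   inflow is zero.
#' @export
box_inflow_difference <- function(base, stroke, g, box) {
  ib <- box_total_inflow(g, base, box)
  is <- box_total_inflow(g, stroke, box)
  if (ib == 0) return(NA_real_)
  (is - ib) / ib
}

box_total_inflow <- function(g, flow, box, q_tol = 1e-12) {
  q <- flow_of(flow, g)
  total <- 0
  for (i in seq_len(nrow(g$vessels))) {
    if (abs(q[i]) <= q_tol) next
    cl <- vessel_centerline(g, g$vessels$id[i])
    cr <- clip_polyline_box(cl, box)$crossings
    for (c_ in cr) {
      entering_geom <- c_ > 0
      # geometric traversal follows the centerline source -> target; with
      # q < 0 the flow traverses it in reverse, flipping enter/leave
      inflow <- if (q[i] >= 0) entering_geom else !entering_geom
      if (inflow) total <- total + abs(q[i])
    }
  }
  # network boundary nodes inside the box act as sources: their injection
  # enters the box without crossing its walls
  bn <- g$nodes[g$nodes$is_boundary, , drop = FALSE]
  if (nrow(bn)) {
    inside <- in_box(as.matrix(bn[, c("x", "y", "z")]), box)
    for (node in bn$id[inside]) {
      vi <- which(g$vessels$source == node | g$vessels$target == node)
      for (v in vi) {
        if (abs(q[v]) <= q_tol) next
        into_net <- if (g$vessels$source[v] == node) q[v] > 0 else q[v] < 0
        if (into_net) total <- total + abs(q[v])
      }
    }
  }
  total
}

#' Length-weighted total flow in a box and flow-decrease count
#'
#' `box_total_flow` sums |q| times the centerline length clipped to the box
#' (tortuosity-aware). `box_total_flow_difference` is its relative change
#' between two fields; `count_flow_decrease` counts in-box vessels whose
#' |q| decreased, excluding the occluded vessels.
#'
#' @inheritParams box_inflow_difference
#' @param vessel_ids optional subset of vessel ids to sum over.
#' @return scalar total (um^4/ms), fraction, or integer count.
#' @export
box_total_flow <- function(g, flow, box, vessel_ids = NULL) {
  q <- flow_of(flow, g)
  ids <- if (is.null(vessel_ids)) g$vessels$id else vessel_ids
  total <- 0
  for (vid in ids) {
    i <- match(vid, g$vessels$id)
    len_in <- clip_polyline_box(vessel_centerline(g, vid), box)$length
    if (len_in > 0) total <- total + abs(q[i]) * len_in
  }
  total
}

#' @rdname box_total_flow
#' @export
box_total_flow_difference <- function(base, stroke, g, box, vessel_ids = NULL) {
  tb <- box_total_flow(g, base, box, vessel_ids)
  ts <- box_total_flow(g, stroke, box, vessel_ids)
  if (tb == 0) return(NA_real_)
  (ts - tb) / tb
}

#' @rdname box_total_flow
#' @param occluded vessel ids excluded from the decrease count.
#' @param q_tol decrease must exceed this magnitude (um^3/ms).
#' @export
count_flow_decrease <- function(base, stroke, g, box, occluded = integer(0),
                                q_tol = 1e-12) {
  qb <- flow_of(base, g); qs <- flow_of(stroke, g)
  n <- 0L
  for (i in seq_len(nrow(g$vessels))) {
    vid <- g$vessels$id[i]
    if (vid %in% occluded) next
    if (clip_polyline_box(vessel_centerline(g, vid), box)$length <= 0) next
    if (abs(qs[i]) < abs(qb[i]) - q_tol) n <- n + 1L
  }
  n
}

#' Topologically supplied tissue volume
#'
#' Discretizes the tissue on a Cartesian grid (cell size 4 um by default)
#' over the network bounding box and assigns each cell center to the
#' nearest vessel centerline point; the supplied volume of a vessel is its
#' cell count times the cell volume. Ties go to the lowest vessel id; cell
#' volumes partition the grid exactly.
#'
#' @param g an [mvn_graph()].
#' @param cell grid cell edge length (um), default 4.
#' @param spacing centerline discretization spacing (um), default 1.3.
#' @param bounds optional 2 x 3 bounds matrix; default the network
#'   bounding box.
#' @return list of class `mvn_tissue_grid`: `volume` (named per-vessel
#'   supplied volume, um^3), `cell`, `n_cells`, `bounds`.
#' @export
supplied_tissue_volume <- function(g, cell = 4, spacing = 1.3, bounds = NULL) {
  disc <- discretize(g, spacing = spacing)
  pts <- disc$points
  if (is.null(bounds)) {
    xyz <- as.matrix(g$nodes[, c("x", "y", "z")])
    bounds <- rbind(apply(xyz, 2, min), apply(xyz, 2, max))
  }
  centers <- lapply(1:3, function(ax) {
    if (bounds[2, ax] - bounds[1, ax] <= cell)
      return(mean(bounds[, ax]))
    seq(bounds[1, ax] + cell / 2, bounds[2, ax], by = cell)
  })
  grid <- as.matrix(expand.grid(centers[[1]], centers[[2]], centers[[3]]))
  # order points by vessel id so spatial ties resolve to the lowest id
  ord <- order(disc$vessel)
  pts <- pts[ord, , drop = FALSE]
  vess <- disc$vessel[ord]
  nn <- .nn_index(pts, grid, cell_size = max(4 * spacing, cell))
  owner <- vess[nn]
  counts <- table(factor(owner, levels = g$vessels$id))
  structure(list(volume = stats::setNames(as.numeric(counts) * cell^3,
                                          g$vessels$id),
                 cell = cell, n_cells = nrow(grid), bounds = bounds),
            class = "mvn_tissue_grid")
}
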