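#' Microstroke configuration
#'
#' Thresholds and selection-criteria parameters of the occlusion protocol.
#' Defaults follow the single-capillary microstroke setup: occlusion
#' diameter 0.01 um, absolute flow-change threshold 0.1 um^3/ms, RBC-flux
#' change threshold 0.2 RBC/s, candidate cylinder radius 444 um, minimum
#' baseline flow 0.16 um^3/ms, minimum hematocrit 0.02, direction-change
#' caps 5% (MSC), 10% (generation ±1), 30% (generations ±2/±3), at least 3
#' segments from the DA and AV main branches (2 in the relaxed variant used
#' for type censuses), and a 0.2 nl bounding-box cap.
#'
#' @param occlusion_diameter um, default 0.01.
#' @param th_abs absolute flow-change threshold (um^3/ms), default 0.1.
#' @param th_rbc RBC-flux change threshold (RBC/s), default 0.2.
#' @param cylinder_radius um, default 444.
#' @param min_flow um^3/ms, default 0.16.
#' @param min_hematocrit default 0.02.
#' @param dirchange_msc,dirchange_gen1,dirchange_gen23 direction-change
#'   frequency caps, defaults 0.05, 0.10, 0.30.
#' @param min_main_branch_segments default 3.
#' @param max_bbox_volume um^3, default 0.2 nl.
#' @param flow_range optional additional `c(min, max)` baseline-flow filter
#'   (um^3/ms), default NULL (disabled).
#' @return list of class `stroke_config`.
#' @export
stroke_config <- function(occlusion_diameter = 0.01, th_abs = 0.1,
                          th_rbc = 0.2, cylinder_radius = 444,
                          min_flow = 0.16, min_hematocrit = 0.02,
                          dirchange_msc = 0.05, dirchange_gen1 = 0.10,
                          dirchange_gen23 = 0.30,
                          min_main_branch_segments = 3,
                          max_bbox_volume = nl_to_um3(0.2),
                          flow_range = NULL) {
  cfg <- as.list(environment())
  stopifnot(occlusion_diameter > 0, th_abs > 0, th_rbc > 0)
  class(cfg) <- "stroke_config"
  cfg
}

#' Occlude vessels
#'
#' Sets the diameter of the given vessels to `d_occ` (default 0.01 um),
#' storing the original diameters so [restore_occlusion()] is an exact
#' inverse. Occluding a boundary vessel is allowed with a warning.
#'
#' @param g an [mvn_graph()].
#' @param vessel_ids vessels to occlude (empty vector leaves `g` unchanged).
#' @param d_occ occlusion diameter (um).
#' @return the modified graph, with attribute `occluded` recording ids and
#'   original diameters.
#' @export
occlude <- function(g, vessel_ids, d_occ = 0.01) {
  stopifnot(d_occ > 0)
  if (!length(vessel_ids)) return(g)
  vi <- match(vessel_ids, g$vessels$id)
  if (anyNA(vi)) stop("unknown vessel id(s): ",
                      paste(vessel_ids[is.na(vi)], collapse = ", "))
  bnodes <- g$nodes$id[g$nodes$is_boundary]
  if (any(g$vessels$source[vi] %in% bnodes | g$vessels$target[vi] %in% bnodes)) {
    warning("occluding boundary vessel(s)")
  }
  prev <- attr(g, "occluded")
  rec <- data.frame(vessel = g$vessels$id[vi], diameter = g$vessels$diameter[vi])
  g$vessels$diameter[vi] <- d_occ
  attr(g, "occluded") <- rbind(prev, rec)
  g
}

#' @rdname occlude
#' @export
restore_occlusion <- function(g) {
  rec <- attr(g, "occluded")
  if (is.null(rec)) return(g)
  vi <- match(rec$vessel, g$vessels$id)
  g$vessels$diameter[vi] <- rec$diameter
  attr(g, "occluded") <- NULL
  g
}

#' Thresholded relative change
#'
#' Relative change of the absolute flow (direction-insensitive), hard-zeroed
#' when the magnitude of the absolute-flow change is below `th_abs`:
#' `(|q_stroke| - |q_base|) / |q_base|`, or 0 when
#' `||q_stroke| - |q_base|| < th_abs`. Undefined (NA) for `q_base = 0`.
#'
#' @param q_base,q_stroke flows (um^3/ms); vectors recycle.
#' @param th_abs absolute threshold (um^3/ms), default 0.1.
#' @return thresholded relative change (fraction), NA where undefined.
#' @export
thresholded_relative_change <- function(q_base, q_stroke, th_abs = 0.1) {
  ab <- abs(q_base); as_ <- abs(q_stroke)
  out <- ifelse(abs(as_ - ab) < th_abs, 0, (as_ - ab) / ab)
  out[ab == 0] <- NA_real_
  out
}

#' Select eligible microstroke candidate capillaries
#'
#' Applies the selection criteria in order and reports the number of
#' surviving candidates after each stage: (1) located within
#' `cylinder_radius` of the x-y centroid of the network; (2) baseline mean
#' flow above `min_flow`; (3) mean hematocrit above `min_hematocrit`;
#' (4) direction-change frequency at most `dirchange_msc` in the candidate,
#' `dirchange_gen1` at generations ±1 and `dirchange_gen23` at generations
#' ±2/±3; (5) at least `min_main_branch_segments` segments from the DA and
#' AV main branches; (6) axis-aligned bounding box at most
#' `max_bbox_volume`. Optionally (7) baseline flow within `flow_range`.
#'
#' @param g an [mvn_graph()] with main branches flagged.
#' @param baseline baseline flow field (steady `mvn_flow` or time-averaged
#'   field with `dirchange` frequencies).
#' @param cfg a [stroke_config()].
#' @param criteria indices of criteria to apply (default all).
#' @return list with `candidates` (vessel ids) and `counts` (named vector
#'   of survivors after each criterion).
#' @export
select_msc_candidates <- function(g, baseline, cfg = stroke_config(),
                                  criteria = 1:7) {
  q <- abs(flow_of(baseline, g))
  ht <- if (!is.null(baseline$h_t)) baseline$h_t else baseline$mean_ht
  dirchange <- baseline$dirchange %||% rep(0, nrow(g$vessels))
  is_cap <- g$vessels$type == "C"
  alive <- which(is_cap)
  counts <- c(capillaries = length(alive))

  if (1 %in% criteria) {
    ctr <- c(mean(g$nodes$x), mean(g$nodes$y))
    mid <- (node_xyz(g, g$vessels$source) + node_xyz(g, g$vessels$target)) / 2
    r <- sqrt((mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2)
    alive <- alive[r[alive] <= cfg$cylinder_radius]
    counts <- c(counts, cylinder = length(alive))
  }
  if (2 %in% criteria) {
    alive <- alive[q[alive] > cfg$min_flow]
    counts <- c(counts, min_flow = length(alive))
  }
  if (3 %in% criteria) {
    alive <- alive[ht[alive] > cfg$min_hematocrit]
    counts <- c(counts, min_hematocrit = length(alive))
  }
  if (4 %in% criteria && any(dirchange > 0)) {
    keep <- vapply(alive, function(vi) {
      if (dirchange[vi] > cfg$dirchange_msc) return(FALSE)
      gens <- generations(g, baseline, g$vessels$id[vi], depth = 3)
      g1 <- match(gens$vessel[abs(gens$generation) == 1], g$vessels$id)
      g23 <- match(gens$vessel[abs(gens$generation) >= 2], g$vessels$id)
      all(dirchange[g1] <= cfg$dirchange_gen1) &&
        all(dirchange[g23] <= cfg$dirchange_gen23)
    }, logical(1))
    alive <- alive[keep]
    counts <- c(counts, dirchange = length(alive))
  } else if (4 %in% criteria) {
    counts <- c(counts, dirchange = length(alive))
  }
  if (5 %in% criteria) {
    dist <- main_branch_distance(g)
    alive <- alive[dist[alive] >= cfg$min_main_branch_segments]
    counts <- c(counts, main_branch = length(alive))
  }
  if (6 %in% criteria) {
    keep <- vapply(alive, function(vi) {
      cl <- vessel_centerline(g, g$vessels$id[vi])
      prod(apply(cl, 2, max) - apply(cl, 2, min)) <= cfg$max_bbox_volume
    }, logical(1))
    alive <- alive[keep]
    counts <- c(counts, bbox = length(alive))
  }
  if (7 %in% criteria && !is.null(cfg$flow_range)) {
    alive <- alive[q[alive] >= cfg$flow_range[1] & q[alive] <= cfg$flow_range[2]]
    counts <- c(counts, flow_range = length(alive))
  }
  list(candidates = g$vessels$id[alive], counts = counts)
}

#' Topological distance to the nearest main-branch vessel
#'
#' Number of segments on the shortest path (ignoring flow direction) from
#' each vessel to the nearest DA/AV main-branch vessel; a vessel incident
#' to a main-branch node has distance 1, main-branch vessels distance 0.
#'
#' @param g an [mvn_graph()].
#' @return integer vector over vessels (Inf when no main branch exists).
#' @export
main_branch_distance <- function(g) {
  mb <- which(g$vessels$main_branch)
  nv <- nrow(g$vessels)
  if (!length(mb)) return(rep(Inf, nv))
  mb_nodes <- unique(c(g$vessels$source[mb], g$vessels$target[mb]))
  ig <- as_igraph(g)
  d_node <- suppressWarnings(
    igraph::distances(ig, v = igraph::V(ig),
                      to = as.character(intersect(mb_nodes, as.integer(igraph::V(ig)$name)))))
  dmin <- apply(d_node, 1, min)
  names(dmin) <- igraph::V(ig)$name
  ds <- dmin[as.character(g$vessels$source)]
  dt <- dmin[as.character(g$vessels$target)]
  out <- pmin(ds, dt) + 1
  out[mb] <- 0
  unname(out)
}

#' Run a single microstroke
#'
#' Computes the baseline and the post-occlusion flow field under identical
#' boundary conditions (and seed, in RBC mode), then derives the
#' thresholded relative flow and RBC-flux changes, reversal and cessation
#' flags, the generation map and the MSC type.
#'
#' @param g an [mvn_graph()].
#' @param bc a [boundary_conditions()].
#' @param msc MSC vessel id.
#' @param cfg a [stroke_config()].
#' @param mode `"steady"` (constant-hematocrit Poiseuille solve) or
#'   `"rbc"` (discrete RBC tracking, time-averaged).
#' @param baseline optional precomputed baseline field (reused across MSCs).
#' @param seed RNG seed for RBC mode.
#' @param ... passed to [run_and_average()] in RBC mode.
#' @return list of class `stroke_result`: `msc`, `msc_type`, `baseline`,
#'   `stroke` fields, `dq`, `dflux`, `reversed`, `ceased`, `generations`.
#' @export
run_single_stroke <- function(g, bc, msc, cfg = stroke_config(),
                              mode = c("steady", "rbc"), baseline = NULL,
                              seed = 1L, ...) {
  mode <- match.arg(mode)
  if (is.null(baseline)) {
    baseline <- if (mode == "steady") solve_pressure_flow(g, bc)
    else run_and_average(g, bc, seed = seed, ...)
  }
  g_occ <- occlude(g, msc, cfg$occlusion_diameter)
  stroke <- if (mode == "steady") solve_pressure_flow(g_occ, bc)
  else run_and_average(g_occ, bc, seed = seed, ...)
  qb <- flow_of(baseline, g); qs <- flow_of(stroke, g)
  dq <- thresholded_relative_change(qb, qs, cfg$th_abs)
  fb <- baseline$rbc_flux %||% baseline$mean_rbc_flux
  fs <- stroke$rbc_flux %||% stroke$mean_rbc_flux
  dflux <- if (!is.null(fb) && !is.null(fs))
    thresholded_relative_change(fb, fs, cfg$th_rbc) else NULL
  q_eps <- 1e-8
  reversed <- sign(qb) * sign(qs) < 0 & abs(qb) > q_eps & abs(qs) > q_eps
  ceased <- abs(qb) > q_eps & abs(qs) <= q_eps
  gens <- generations(g, baseline, msc)
  structure(list(msc = msc,
                 msc_type = classify_msc_type(g, baseline, msc),
                 baseline = baseline, stroke = stroke,
                 dq = dq, dflux = dflux,
                 reversed = reversed, ceased = ceased,
                 generations = gens, mode = mode, config = cfg),
            class = "stroke_result")
}

#' @export
print.stroke_result <- function(x, ...) {
  cat(sprintf("microstroke at vessel %d (type %s, %s mode): %d reversals, %d cessations\n",
              x$msc, x$msc_type %||% "NA", x$mode, sum(x$reversed), sum(x$ceased)))
  invisible(x)
}

#' Sequential multi-capillary occlusion
#'
#' Starting from a single occluded MSC, repeatedly adds the two
#' lowest-|flow| non-occluded capillaries inside the analysis box around
#' the MSC (volume factor 1.5, i.e. 0.3 nl by default) and re-solves, until
#' `n_target` occlusions. Stops early (flagged) when fewer than two
#' candidates remain.
#'
#' @inheritParams run_single_stroke
#' @param box_volume analysis-box volume (um^3), default 0.3 nl.
#' @param n_target final number of occlusions, default 9.
#' @param min_box_capillaries required capillaries in the box, default 12.
#' @return list of `stroke_result`-like stages (one per occlusion count
#'   1, 3, 5, ..., `n_target`), each with elements `n_occluded`, `occluded`,
#'   `stroke` field; attribute `stopped_early` when applicable.
#' @export
run_multi_occlusion <- function(g, bc, msc, cfg = stroke_config(),
                                box_volume = nl_to_um3(0.3), n_target = 9,
                                min_box_capillaries = 12,
                                mode = "steady", baseline = NULL, seed = 1L,
                                ...) {
  if (is.null(baseline)) {
    baseline <- if (mode == "steady") solve_pressure_flow(g, bc)
    else run_and_average(g, bc, seed = seed, ...)
  }
  box <- msc_box(g, msc, box_volume)
  bnodes <- g$nodes$id[g$nodes$is_boundary]
  inbox <- vapply(seq_len(nrow(g$vessels)), function(i) {
    g$vessels$type[i] == "C" &&
      # boundary stubs carry prescribed pressures; occluding them would
      # remove a boundary condition rather than mimic an interior stall
      !(g$vessels$source[i] %in% bnodes || g$vessels$target[i] %in% bnodes) &&
      clip_polyline_box(vessel_centerline(g, g$vessels$id[i]), box)$length > 0
  }, logical(1))
  box_caps <- g$vessels$id[inbox]
  if (length(setdiff(box_caps, msc)) <= min_box_capillaries) {
    stop("analysis box holds ", length(setdiff(box_caps, msc)),
         " capillaries; more than ", min_box_capillaries, " required")
  }
  occluded <- msc
  stages <- list()
  stopped <- FALSE
  repeat {
    g_occ <- occlude(g, occluded, cfg$occlusion_diameter)
    fld <- if (mode == "steady") solve_pressure_flow(g_occ, bc)
    else run_and_average(g_occ, bc, seed = seed, ...)
    stages[[length(stages) + 1L]] <- list(
      n_occluded = length(occluded), occluded = occluded, stroke = fld,
      box = box)
    if (length(occluded) >= n_target) break
    cand <- setdiff(box_caps, occluded)
    if (length(cand) < 2L) { stopped <- TRUE; break }
    qa <- abs(flow_of(fld, g)[match(cand, g$vessels$id)])
    nxt <- cand[order(qa, cand)][1:2]
    occluded <- c(occluded, nxt)
  }
  attr(stages, "stopped_early") <- stopped
  attr(stages, "baseline") <- baseline
  stages
}
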