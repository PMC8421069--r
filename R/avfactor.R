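#' Discretize vessel centerlines into analysis points
#'
#' Arc-length-uniform resampling of every centerline with
#' `ceil(L / spacing) + 1` points per vessel (endpoints included), so the
#' actual spacing never exceeds the nominal one.
#'
#' @param g an [mvn_graph()].
#' @param spacing nominal point spacing (um), default 1.3.
#' @param vessel_ids optional subset.
#' @return list: `points` (n x 3 matrix), `vessel` (owning vessel id per
#'   point), `arc` (arc position per point, um).
#' @export
discretize <- function(g, spacing = 1.3, vessel_ids = NULL) {
  ids <- if (is.null(vessel_ids)) g$vessels$id else vessel_ids
  pts <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    cl <- vessel_centerline(g, ids[k])
    L <- g$vessels$length[match(ids[k], g$vessels$id)]
    n <- ceiling(L / spacing) + 1
    pts[[k]] <- cbind(resample_polyline(cl, n), arc = seq(0, 1, length.out = n))
  }
  npts <- vapply(pts, nrow, integer(1))
  m <- do.call(rbind, pts)
  list(points = m[, 1:3, drop = FALSE], vessel = rep(ids, npts),
       arc = m[, 4])
}

resample_polyline <- function(cl, n) {
  seg <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, length.out = n)
  out <- matrix(NA_real_, n, 3)
  for (ax in 1:3) out[, ax] <- stats::approx(cum, cl[, ax], xout = s)$y
  out
}

#' AV-factor of capillaries along DA-to-AV flow paths
#'
#' For each capillary on at least one DA-to-AV flow path, collects the
#' multiset of upstream path lengths (sums of vessel lengths over all flow
#' paths from any DA endpoint to the capillary's upstream node) and the
#' downstream path lengths to all AV endpoints, and computes
#' `median(dist_DA) / (median(dist_DA) + median(dist_AV))` — near 0 for
#' arteriole-sided, near 1 for venule-sided capillaries. Exhaustive
#' enumeration is used up to `max_paths` per side; beyond that, `n_sample`
#' paths are drawn uniformly via DP path-count weights and the medians are
#' estimated from the sample (flagged in the `sampled` column).
#'
#' @param g an [mvn_graph()].
#' @param flow flow field on `g`.
#' @param dag optional precomputed [build_flow_dag()].
#' @param max_paths exhaustive-enumeration cap per capillary side,
#'   default 1e5.
#' @param n_sample sample size in sampling mode, default 1e4.
#' @param mode `"paths"` (median over the path-length multiset, default) or
#'   `"endpoints"` (median over per-endpoint shortest distances).
#' @param seed seed for sampling mode.
#' @return data.frame `vessel`, `av_factor` (NA when unassigned),
#'   `med_da`, `med_av`, `sampled`.
#' @export
compute_av_factor <- function(g, flow, dag = NULL, max_paths = 1e5,
                              n_sample = 1e4, mode = c("paths", "endpoints"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(dag)) dag <- build_flow_dag(g, flow)
  caps <- which(g$vessels$type == "C")
  out <- data.frame(vessel = g$vessels$id[caps], av_factor = NA_real_,
                    med_da = NA_real_, med_av = NA_real_, sampled = FALSE)
  ei <- match(g$vessels$id[caps], dag$edges$vessel)
  present <- !is.na(ei)
  if (!any(present)) return(out)
  nodes <- sort(unique(c(dag$edges$from, dag$edges$to)))
  nidx <- function(x) match(x, nodes) - 1L
  vlen <- g$vessels$length[match(dag$edges$vessel, g$vessels$id)]
  term_da <- logical(length(nodes)); term_da[match(intersect(dag$da_endpoints, nodes), nodes)] <- TRUE
  term_av <- logical(length(nodes)); term_av[match(intersect(dag$av_endpoints, nodes), nodes)] <- TRUE
  tails <- nidx(dag$edges$from[ei[present]])
  heads <- nidx(dag$edges$to[ei[present]])
  if (mode == "paths") {
    res <- with_seed(seed, {
      # upstream: walk against the flow (reversed edges) to the DA endpoints
      up <- .path_length_medians(length(nodes), nidx(dag$edges$to),
                                 nidx(dag$edges$from), vlen, term_da,
                                 tails, max_paths, as.integer(n_sample))
      dn <- .path_length_medians(length(nodes), nidx(dag$edges$from),
                                 nidx(dag$edges$to), vlen, term_av,
                                 heads, max_paths, as.integer(n_sample))
      list(up = up, dn = dn)
    })
    up <- res$up; dn <- res$dn
    out$med_da[present] <- up$median
    out$med_av[present] <- dn$median
    out$sampled[present] <- up$sampled | dn$sampled
  } else {
    idx <- prepare_path_index(dag, g)
    rows <- which(present)
    for (k in seq_along(rows)) {
      r <- rows[k]
      upl <- endpoint_shortest(idx, dag$edges$from[ei[r]], "up")
      dnl <- endpoint_shortest(idx, dag$edges$to[ei[r]], "down")
      if (length(upl)) out$med_da[r] <- stats::median(upl)
      if (length(dnl)) out$med_av[r] <- stats::median(dnl)
    }
  }
  ok <- !is.na(out$med_da) & !is.na(out$med_av)
  out$av_factor[ok] <- out$med_da[ok] / (out$med_da[ok] + out$med_av[ok])
  out
}

prepare_path_index <- function(dag, g) {
  vlen <- g$vessels$length[match(dag$edges$vessel, g$vessels$id)]
  list(edges = dag$edges, len = vlen,
       da = dag$da_endpoints, av = dag$av_endpoints)
}

endpoint_shortest <- function(idx, node, direction) {
  terminals <- if (direction == "up") idx$da else idx$av
  el <- if (direction == "up") cbind(as.character(idx$edges$to), as.character(idx$edges$from))
  else cbind(as.character(idx$edges$from), as.character(idx$edges$to))
  ig <- igraph::graph_from_edgelist(el, directed = TRUE)
  igraph::E(ig)$weight <- idx$len
  terms <- terminals[as.character(terminals) %in% igraph::V(ig)$name]
  if (!length(terms) || !as.character(node) %in% igraph::V(ig)$name) return(numeric(0))
  d <- suppressWarnings(igraph::distances(ig, v = as.character(node),
                                          to = as.character(terms), mode = "out"))
  d <- d[is.finite(d)]
  as.numeric(d)
}

#' Nearest-distance maps for venule-sided capillary points
#'
#' For every discretization point of a venule-sided capillary (AV-factor
#' >= 0.5), computes the shortest distance to any vessel point of another
#' vessel, the shortest distance to an arteriole-sided capillary point
#' (AV-factor < 0.5), and the distance factor (their ratio, >= 1 whenever
#' the nearest vessel is not arteriole-sided).
#'
#' @param disc a [discretize()] result.
#' @param avmap a [compute_av_factor()] result.
#' @param flag_above distance factors above this are flagged, default 10.
#' @return data.frame `vessel`, `d_any`, `d_arteriole`, `distance_factor`,
#'   `flagged`.
#' @export
distance_maps <- function(disc, avmap, flag_above = 10) {
  av <- avmap$av_factor[match(disc$vessel, avmap$vessel)]
  ven_pts <- which(!is.na(av) & av >= 0.5)
  art_vessels <- avmap$vessel[!is.na(avmap$av_factor) & avmap$av_factor < 0.5]
  art_pts <- which(disc$vessel %in% art_vessels)
  if (!length(ven_pts)) {
    return(data.frame(vessel = integer(), d_any = numeric(),
                      d_arteriole = numeric(), distance_factor = numeric(),
                      flagged = logical()))
  }
  q <- disc$points[ven_pts, , drop = FALSE]
  d_any <- numeric(length(ven_pts))
  for (k in seq_along(ven_pts)) {
    other <- disc$vessel != disc$vessel[ven_pts[k]]
    dd <- sqrt(colSums((t(disc$points[other, , drop = FALSE]) - q[k, ])^2))
    d_any[k] <- if (length(dd)) min(dd) else NA_real_
  }
  if (length(art_pts)) {
    d_art <- numeric(length(ven_pts))
    for (k in seq_along(ven_pts)) {
      keep <- art_pts[disc$vessel[art_pts] != disc$vessel[ven_pts[k]]]
      dd <- sqrt(colSums((t(disc$points[keep, , drop = FALSE]) - q[k, ])^2))
      d_art[k] <- if (length(dd)) min(dd) else NA_real_
    }
  } else {
    d_art <- rep(NA_real_, length(ven_pts))
  }
  df <- d_art / d_any
  data.frame(vessel = disc$vessel[ven_pts], d_any = d_any,
             d_arteriole = d_art, distance_factor = df,
             flagged = !is.na(df) & df > flag_above)
}

#' Moving-sphere and tiled-cube scans of the AV-factor field
#'
#' `sphere_scan`: for each venule-sided capillary, a sphere of radius `r`
#' is moved along its discretization points; the mean AV-factor over all
#' AV-factored capillary points inside any of the spheres is compared with
#' the capillary's own AV-factor. Capillaries are eligible only when at
#' least `min_coverage` of the in-sphere points carry an AV-factor.
#' `cube_scan`: tiles the network bounding box with cubes of the given side
#' (half-side overlap) and averages the AV-factor per cube over the
#' AV-factored capillaries inside; cubes need at least `min_capillaries`
#' AV-factored capillaries and `min_coverage` coverage.
#'
#' @param g an [mvn_graph()].
#' @param avmap a [compute_av_factor()] result.
#' @param disc optional precomputed [discretize()] result.
#' @param r sphere radius (um), default 50.
#' @param side cube side length (um).
#' @param min_coverage minimum assigned fraction, default 0.5.
#' @param min_capillaries minimum AV-factored capillaries per cube,
#'   default 4.
#' @return data.frame per capillary (sphere) or per cube.
#' @export
sphere_scan <- function(g, avmap, disc = NULL, r = 50, min_coverage = 0.5) {
  if (is.null(disc)) disc <- discretize(g)
  cap_pts <- disc$vessel %in% avmap$vessel
  pts <- disc$points[cap_pts, , drop = FALSE]
  pvessel <- disc$vessel[cap_pts]
  av_pt <- avmap$av_factor[match(pvessel, avmap$vessel)]
  ven <- avmap$vessel[!is.na(avmap$av_factor) & avmap$av_factor >= 0.5]
  if (!length(ven)) {
    return(data.frame(vessel = integer(), own = numeric(),
                      sphere_mean = numeric(), coverage = numeric(),
                      eligible = logical(), difference = numeric()))
  }
  out <- data.frame(vessel = ven, own = avmap$av_factor[match(ven, avmap$vessel)],
                    sphere_mean = NA_real_, coverage = NA_real_,
                    eligible = FALSE)
  for (k in seq_along(ven)) {
    centers <- disc$points[disc$vessel == ven[k], , drop = FALSE]
    # union over the capillary's spheres
    inside <- rep(FALSE, nrow(pts))
    for (c_ in seq_len(nrow(centers))) {
      dd <- (pts[, 1] - centers[c_, 1])^2 + (pts[, 2] - centers[c_, 2])^2 +
        (pts[, 3] - centers[c_, 3])^2
      inside <- inside | dd <= r^2
    }
    n_in <- sum(inside)
    n_av <- sum(inside & !is.na(av_pt))
    out$coverage[k] <- if (n_in) n_av / n_in else NA_real_
    out$sphere_mean[k] <- if (n_av) mean(av_pt[inside], na.rm = TRUE) else NA_real_
    out$eligible[k] <- n_in > 0 && out$coverage[k] >= min_coverage
  }
  out$difference <- out$sphere_mean - out$own
  out
}

#' @rdname sphere_scan
#' @export
cube_scan <- function(g, avmap, disc = NULL, side = 60, min_coverage = 0.5,
                      min_capillaries = 4) {
  if (is.null(disc)) disc <- discretize(g)
  xyz <- as.matrix(g$nodes[, c("x", "y", "z")])
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  starts <- lapply(1:3, function(ax) {
    s <- seq(lo[ax], max(hi[ax] - side, lo[ax]), by = side / 2)
    s
  })
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  av <- avmap$av_factor
  res <- lapply(seq_len(nrow(grid)), function(i) {
    b0 <- as.numeric(grid[i, ]); b1 <- b0 + side
    # a capillary is in the cube when any of its points is
    inpt <- disc$points[, 1] >= b0[1] & disc$points[, 1] <= b1[1] &
      disc$points[, 2] >= b0[2] & disc$points[, 2] <= b1[2] &
      disc$points[, 3] >= b0[3] & disc$points[, 3] <= b1[3]
    vids <- unique(disc$vessel[inpt])
    vids <- vids[vids %in% avmap$vessel]
    if (!length(vids)) return(NULL)
    avs <- av[match(vids, avmap$vessel)]
    n_with <- sum(!is.na(avs))
    coverage <- n_with / length(vids)
    data.frame(x = b0[1], y = b0[2], z = b0[3], n_capillaries = length(vids),
               n_with_av = n_with, coverage = coverage,
               mean_av = if (n_with) mean(avs, na.rm = TRUE) else NA_real_,
               eligible = n_with >= min_capillaries & coverage >= min_coverage)
  })
  do.call(rbind, res)
}
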