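#' Discrete red blood cell tracking
#'
#' Simulates individual RBCs advected through the network: vessel
#' hematocrits are recomputed from the tracked cells, the pressure/flow
#' field is re-solved with the hematocrit-dependent viscosity every step,
#' and RBCs are routed at divergent bifurcations by the empirical phase
#' separation law (parent diameter > 10 um) or the single-file
#' largest-pressure-force rule (< 10 um). The unequal partitioning feeds
#' back on the resistances and produces the fluctuating flow field whose
#' time average the analyses use.
#'
#' @param g an [mvn_graph()].
#' @param bc a [boundary_conditions()].
#' @param rbc_volume RBC volume (um^3), default 49 (mouse).
#' @param seed integer seed controlling initial RBC placement and
#'   stochastic routing.
#' @param prefill start from vessels filled to the tube hematocrit implied
#'   by the inflow discharge hematocrit (default TRUE; FALSE starts empty).
#' @return a simulation state (class `rbc_state`).
#' @export
rbc_init <- function(g, bc, rbc_volume = 49, seed = 1L, prefill = TRUE) {
  nv <- nrow(g$vessels)
  lumen <- lumen_volume(g)
  state <- list(g = g, bc = bc, rbc_volume = rbc_volume,
                time = 0, steps = 0L,
                vessel = integer(0), pos = numeric(0),
                perfused = rep(0, nv),
                sign_prev = rep(0, nv), dirchanges = rep(0L, nv),
                created = 0L, destroyed = 0L,
                inject_acc = NULL,
                sum_q = rep(0, nv), sum_absq = rep(0, nv),
                sum_ht = rep(0, nv), sum_flux = rep(0, nv),
                avg_time = 0, avg_steps = 0L, avg_changes = rep(0L, nv))
  if (prefill && bc$inflow_hematocrit > 0) {
    ht0 <- fahraeus_tube_hematocrit(g$vessels$diameter, bc$inflow_hematocrit)
    n0 <- round(ht0 * lumen / rbc_volume)
    state <- with_seed(seed, {
      v <- rep(seq_len(nv), n0)
      p <- stats::runif(length(v)) * g$vessels$length[v]
      state$vessel <- v; state$pos <- p
      state
    })
    state$created <- length(state$vessel)
  }
  state$seed <- seed
  class(state) <- "rbc_state"
  state
}

state_hematocrit <- function(state) {
  g <- state$g
  lumen <- lumen_volume(g)
  n_per <- tabulate(state$vessel, nbins = nrow(g$vessels))
  h_t <- pmin(n_per * state$rbc_volume / lumen, 0.9)
  h_d <- ifelse(h_t > 0,
                fahraeus_discharge_from_tube(g$vessels$diameter, h_t), 0)
  list(h_t = h_t, h_d = pmin(h_d, 0.9))
}

#' Advance the RBC simulation by one time step
#'
#' Re-solves the flow field from the current hematocrits, advects every RBC
#' by its cell velocity (bulk velocity times `H_d/H_t`, the Fahraeus
#' velocity ratio), routes cells crossing a node by the bifurcation rules,
#' injects cells at inflow boundaries to match the inflow discharge
#' hematocrit, and updates the perfusion and direction-change bookkeeping.
#' RBCs are created only at inflow boundaries and destroyed only at
#' outflow boundaries.
#'
#' @param state an `rbc_state`.
#' @param dt time step (ms); default the stability bound
#'   `0.8 min(L / v_rbc)` capped at 1 ms.
#' @param averaging accumulate time averages (used by [run_and_average()]).
#' @return the advanced state, with element `flow` holding the current
#'   `mvn_flow`.
#' @export
rbc_step <- function(state, dt = NULL, averaging = FALSE) {
  g <- state$g
  nv <- nrow(g$vessels)
  hem <- state_hematocrit(state)
  flow <- solve_pressure_flow(g, state$bc, h_d = hem$h_d,
                              rbc_volume = state$rbc_volume, check = FALSE)
  flow$h_t <- hem$h_t
  area <- pi * g$vessels$diameter^2 / 4
  v_bulk <- flow$q / area                               # um/ms, signed
  ratio <- fahraeus_ratio(g$vessels$diameter, pmin(hem$h_d, 0.9))
  v_rbc <- v_bulk / ratio
  if (is.null(dt)) {
    perfused <- abs(v_rbc) > 1e-9
    dt <- if (any(perfused))
      min(0.8 * min(g$vessels$length[perfused] / abs(v_rbc[perfused])), 1) else 1
  }

  # advect
  if (length(state$vessel)) {
    state$pos <- state$pos + v_rbc[state$vessel] * dt
    # route cells that crossed a node (single hop per step; dt respects the
    # stability bound so multiple hops are rare and clamped)
    over <- which(state$pos > g$vessels$length[state$vessel] | state$pos < 0)
    if (length(over)) {
      keep <- rep(TRUE, length(over))
      p_node <- stats::setNames(flow$pressure, g$nodes$id)
      for (ii in seq_along(over)) {
        k <- over[ii]
        vi <- state$vessel[k]
        exit_target <- state$pos[k] > g$vessels$length[vi]
        node <- if (exit_target) g$vessels$target[vi] else g$vessels$source[vi]
        excess <- if (exit_target) state$pos[k] - g$vessels$length[vi] else -state$pos[k]
        res <- route_rbc(state, flow, node, vi, p_node)
        if (is.na(res)) {
          if (g$nodes$is_boundary[match(node, g$nodes$id)]) {
            keep[ii] <- FALSE           # leaves the network
            state$destroyed <- state$destroyed + 1L
          } else {
            # stagnant interior node: wait at the end of the vessel
            state$pos[k] <- if (exit_target) g$vessels$length[vi] else 0
          }
        } else {
          enters_at_source <- g$vessels$source[res] == node
          dist_in <- min(excess, g$vessels$length[res])
          state$vessel[k] <- res
          state$pos[k] <- if (enters_at_source) dist_in else
            g$vessels$length[res] - dist_in
        }
      }
      if (any(!keep)) {
        drop <- over[!keep]
        state$vessel <- state$vessel[-drop]
        state$pos <- state$pos[-drop]
      }
    }
  }

  # injection at inflow boundary vessels
  binfo <- inflow_boundary_vessels(g, flow)
  if (is.null(state$inject_acc)) {
    state$inject_acc <- with_seed(state$seed + 1L,
                                  stats::runif(nrow(g$vessels)))
  }
  hd_in <- state$bc$inflow_hematocrit
  if (hd_in > 0 && length(binfo$vessel)) {
    for (ii in seq_along(binfo$vessel)) {
      vi <- binfo$vessel[ii]
      rate <- abs(flow$q[vi]) * hd_in / state$rbc_volume   # RBC per ms
      state$inject_acc[vi] <- state$inject_acc[vi] + rate * dt
      while (state$inject_acc[vi] >= 1) {
        state$inject_acc[vi] <- state$inject_acc[vi] - 1
        state$vessel <- c(state$vessel, vi)
        state$pos <- c(state$pos, if (binfo$enters_at_source[ii]) 0
                       else g$vessels$length[vi])
        state$created <- state$created + 1L
      }
    }
  }

  # bookkeeping
  state$perfused <- state$perfused + abs(flow$q) * dt
  sgn <- sign(flow$q) * (abs(flow$q) > 1e-10)
  changed <- sgn != 0 & state$sign_prev != 0 & sgn != state$sign_prev
  state$dirchanges <- state$dirchanges + changed
  state$sign_prev <- ifelse(sgn != 0, sgn, state$sign_prev)
  state$steps <- state$steps + 1L
  state$time <- state$time + dt
  if (averaging) {
    state$sum_q <- state$sum_q + flow$q * dt
    state$sum_absq <- state$sum_absq + abs(flow$q) * dt
    state$sum_ht <- state$sum_ht + hem$h_t * dt
    state$sum_flux <- state$sum_flux + flow$rbc_flux * dt
    state$avg_time <- state$avg_time + dt
    state$avg_steps <- state$avg_steps + 1L
    state$avg_changes <- state$avg_changes + changed
  }
  state$flow <- flow
  state
}

# which daughter does an RBC leaving `vi` through `node` enter? NA when the
# node has no outflow vessel (boundary or stagnant)
route_rbc <- function(state, flow, node, vi, p_node) {
  g <- state$g
  inc_v <- which(g$vessels$source == node | g$vessels$target == node)
  inc_v <- setdiff(inc_v, vi)
  if (!length(inc_v)) return(NA_integer_)
  q <- flow$q
  leaves <- (g$vessels$source[inc_v] == node & q[inc_v] > 1e-12) |
    (g$vessels$target[inc_v] == node & q[inc_v] < -1e-12)
  daughters <- inc_v[leaves]
  if (!length(daughters)) return(NA_integer_)
  if (length(daughters) == 1L) return(daughters)
  d_parent <- g$vessels$diameter[vi]
  if (length(daughters) == 2L && d_parent > 10) {
    fq1 <- abs(q[daughters[1]]) / (abs(q[daughters[1]]) + abs(q[daughters[2]]))
    hd_parent <- min(flow$h_d[vi], 0.9)
    fe1 <- phase_separation_fraction(fq1, d_parent,
                                     g$vessels$diameter[daughters[1]],
                                     g$vessels$diameter[daughters[2]],
                                     hd_parent)
    return(if (stats::runif(1) < fe1) daughters[1] else daughters[2])
  }
  select_daughter_single_file(g, flow, node, daughters, p_node)
}

#' Single-file daughter selection
#'
#' At a divergent bifurcation with a parent thinner than 10 um the RBC
#' follows the daughter with the largest pressure force, implemented as the
#' pressure drop across the daughter times its cross-sectional area
#' (configurable to pressure drop only); ties break to the lowest vessel
#' id.
#'
#' @param g an [mvn_graph()].
#' @param flow current `mvn_flow`.
#' @param node the bifurcation node id.
#' @param daughters candidate outflow vessel row indices (default: all
#'   outflow vessels at `node`).
#' @param p_node named node-pressure lookup (internal use).
#' @param rule `"dp_area"` (default) or `"dp"`.
#' @return the chosen vessel row index.
#' @export
select_daughter_single_file <- function(g, flow, node, daughters = NULL,
                                        p_node = NULL,
                                        rule = c("dp_area", "dp")) {
  rule <- match.arg(rule)
  if (is.null(p_node)) p_node <- stats::setNames(flow$pressure, g$nodes$id)
  if (is.null(daughters)) {
    inc_v <- which(g$vessels$source == node | g$vessels$target == node)
    q <- flow$q
    leaves <- (g$vessels$source[inc_v] == node & q[inc_v] > 1e-12) |
      (g$vessels$target[inc_v] == node & q[inc_v] < -1e-12)
    daughters <- inc_v[leaves]
    if (!length(daughters)) return(NA_integer_)
  }
  other <- ifelse(g$vessels$source[daughters] == node,
                  g$vessels$target[daughters], g$vessels$source[daughters])
  dp <- abs(p_node[as.character(node)] - p_node[as.character(other)])
  force <- if (rule == "dp_area")
    dp * pi * g$vessels$diameter[daughters]^2 / 4 else dp
  daughters[order(-force, g$vessels$id[daughters])][1]
}

inflow_boundary_vessels <- function(g, flow) {
  bnodes <- g$nodes$id[g$nodes$is_boundary]
  vi <- which(g$vessels$source %in% bnodes | g$vessels$target %in% bnodes)
  res <- lapply(vi, function(v) {
    bn <- intersect(c(g$vessels$source[v], g$vessels$target[v]), bnodes)
    for (node in bn) {
      at_source <- g$vessels$source[v] == node
      inflow <- (at_source & flow$q[v] > 1e-12) ||
        (!at_source && flow$q[v] < -1e-12)
      if (inflow) return(data.frame(vessel = v, enters_at_source = at_source))
    }
    NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(vessel = integer(), enters_at_source = logical())
  else out
}

#' Turnover time of the current simulation
#'
#' The first time at which at least `frac` (default 85%) of all vessels
#' have been completely perfused at least once, i.e. their cumulative
#' perfused volume reached their own lumen volume.
#'
#' @param state an `rbc_state` that has been stepped past the criterion.
#' @param frac required fraction of vessels, default 0.85.
#' @return turnover time (ms); error when the criterion has not been met.
#' @export
turnover_time <- function(state, frac = 0.85) {
  if (is.null(state$turnover)) {
    stop("turnover criterion not reached yet; run the simulation further")
  }
  state$turnover
}

turnover_reached <- function(state, frac = 0.85) {
  lumen <- lumen_volume(state$g)
  mean(state$perfused >= lumen) >= frac
}

#' Run the RBC simulation and average over turnover times
#'
#' Steps the simulation until the turnover criterion is met (85% of vessels
#' completely perfused once), treats that first turnover as burn-in, and
#' averages the flow field over the following `n_turnovers` turnover times.
#' With no RBCs present (inflow hematocrit 0 and no prefill residue) the
#' average equals the steady solve exactly.
#'
#' @inheritParams rbc_init
#' @param n_turnovers number of turnover times to average over, default 10.
#' @param max_steps step cap per phase, default 2e4.
#' @return class `mvn_tavg`: per-vessel `mean_q`, `mean_abs_q`, `mean_ht`,
#'   `mean_rbc_flux`, `dirchange` (direction-change frequency), plus
#'   `turnover` (ms), `window` (ms), `state` (final `rbc_state`).
#' @export
run_and_average <- function(g, bc, n_turnovers = 10, seed = 1L,
                            rbc_volume = 49, prefill = TRUE,
                            max_steps = 2e4) {
  state <- rbc_init(g, bc, rbc_volume = rbc_volume, seed = seed,
                    prefill = prefill)
  state <- with_seed(seed + 2L, {
    # burn-in: one full turnover
    while (!turnover_reached(state)) {
      state <- rbc_step(state)
      if (state$steps > max_steps) {
        no_flow <- mean(state$perfused < lumen_volume(g))
        stop(sprintf(
          "turnover criterion unreachable within %d steps (%.0f%% of vessels not fully perfused)",
          max_steps, 100 * no_flow))
      }
    }
    state$turnover <- state$time
    window <- n_turnovers * state$turnover
    t_end <- state$time + window
    while (state$time < t_end && state$avg_steps < max_steps) {
      state <- rbc_step(state, averaging = TRUE)
    }
    state
  })
  w <- max(state$avg_time, .Machine$double.eps)
  structure(list(
    vessel = g$vessels$id,
    mean_q = state$sum_q / w,
    mean_abs_q = state$sum_absq / w,
    mean_ht = state$sum_ht / w,
    mean_rbc_flux = state$sum_flux / w,
    dirchange = state$avg_changes / max(state$avg_steps, 1L),
    turnover = state$turnover, window = state$avg_time,
    n_turnovers = n_turnovers, state = state),
    class = "mvn_tavg")
}

#' @export
print.mvn_tavg <- function(x, ...) {
  cat(sprintf("time-averaged field: window %.1f ms (%d x turnover %.1f ms), median |q| %.3g um^3/ms\n",
              x$window, x$n_turnovers, x$turnover,
              stats::median(x$mean_abs_q)))
  invisible(x)
}
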