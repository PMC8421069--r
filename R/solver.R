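#' Boundary conditions for the pressure solver
#'
#' Dirichlet pressures at every boundary (degree-1) node plus the inflow
#' discharge hematocrit. Pressures may be given in mmHg (converted on
#' construction) or Pa.
#'
#' @param node node ids.
#' @param pressure pressures at those nodes.
#' @param unit `"Pa"` or `"mmHg"`.
#' @param inflow_hematocrit discharge hematocrit of inflowing blood, in
#'   [0, 1); default 0.3.
#' @return object of class `mvn_bc`.
#' @export
boundary_conditions <- function(node, pressure, unit = c("Pa", "mmHg"),
                                inflow_hematocrit = 0.3) {
  unit <- match.arg(unit)
  stopifnot(length(node) == length(pressure), all(is.finite(pressure)),
            inflow_hematocrit >= 0, inflow_hematocrit < 1)
  p <- if (unit == "mmHg") mmHg_to_Pa(pressure) else pressure
  structure(list(node = as.integer(node), pressure = p,
                 inflow_hematocrit = inflow_hematocrit),
            class = "mvn_bc")
}

#' @export
print.mvn_bc <- function(x, ...) {
  cat(sprintf("mvn boundary conditions: %d nodes, p in [%.1f, %.1f] mmHg, inflow Hd %.2f\n",
              length(x$node), Pa_to_mmHg(min(x$pressure)),
              Pa_to_mmHg(max(x$pressure)), x$inflow_hematocrit))
  invisible(x)
}

# Poiseuille conductance in um^3 / (ms Pa):
#   pi D^4 / (128 L mu mu_rel), D and L in um, mu in Pa s (= Pa ms * 1e3)
vessel_conductance <- function(d, l, mu, mu_rel) {
  pi * d^4 / (128 * l * mu * mu_rel) * 1e-3
}

#' Steady pressure/flow solution under Poiseuille's law
#'
#' Assembles the nodal continuity equations with Poiseuille conductances
#' `pi D^4 / (128 L mu mu_rel)` and solves the Dirichlet-reduced sparse
#' symmetric positive-definite system for the interior pressures. Flow
#' `q_ij = g_ij (p_i - p_j)` is signed by the source-to-target orientation
#' of each vessel; units um^3/ms.
#'
#' @param g an [mvn_graph()].
#' @param bc a [boundary_conditions()] covering every boundary node.
#' @param h_d per-vessel discharge hematocrit (scalar or vector); default
#'   the boundary-condition inflow hematocrit everywhere.
#' @param mu plasma viscosity (Pa s), default 1.2e-3.
#' @param viscosity `"pries"` (hematocrit- and diameter-dependent relative
#'   viscosity) or `"plasma"` (relative viscosity 1).
#' @return object of class `mvn_flow`: node `pressure` (Pa, in node-table
#'   order), vessel `q` (um^3/ms), `h_d`, `h_t`, `rbc_flux` (RBC/s, with the
#'   default 49 um^3 RBC volume), and the continuity `residual`.
#' @export
solve_pressure_flow <- function(g, bc, h_d = NULL, mu = 1.2e-3,
                                viscosity = c("pries", "plasma"),
                                rbc_volume = 49, check = TRUE) {
  viscosity <- match.arg(viscosity)
  nv <- nrow(g$vessels)
  if (is.null(h_d)) h_d <- rep(bc$inflow_hematocrit, nv)
  if (length(h_d) == 1L) h_d <- rep(h_d, nv)
  mu_rel <- if (viscosity == "pries")
    relative_effective_viscosity(g$vessels$diameter, h_d) else rep(1, nv)
  cond <- vessel_conductance(g$vessels$diameter, g$vessels$length, mu, mu_rel)

  node_ids <- g$nodes$id
  n <- length(node_ids)
  si <- match(g$vessels$source, node_ids)
  ti <- match(g$vessels$target, node_ids)
  bidx <- match(bc$node, node_ids)
  if (anyNA(bidx)) stop("boundary condition on unknown node id")
  is_dirichlet <- rep(FALSE, n); is_dirichlet[bidx] <- TRUE
  pfix <- rep(NA_real_, n); pfix[bidx] <- bc$pressure

  free <- which(!is_dirichlet)
  if (check) {
    # every connected component must touch a Dirichlet node
    ig <- as_igraph(g)
    comp <- igraph::components(ig)
    memb <- comp$membership[as.character(node_ids)]
    has_bc <- tapply(is_dirichlet, memb, any)
    if (any(!has_bc, na.rm = TRUE)) {
      stop("component(s) without boundary pressure: ",
           paste(names(has_bc)[!has_bc], collapse = ", "))
    }
  }

  # Laplacian assembly
  L <- Matrix::sparseMatrix(
    i = c(si, ti, si, ti), j = c(ti, si, si, ti),
    x = c(-cond, -cond, cond, cond), dims = c(n, n))
  p <- numeric(n)
  p[bidx] <- bc$pressure
  if (length(free)) {
    A <- L[free, free, drop = FALSE]
    b <- -(L[free, bidx, drop = FALSE] %*% bc$pressure)
    p[free] <- as.numeric(Matrix::solve(A, b))
  }
  q <- cond * (p[si] - p[ti])
  h_t <- fahraeus_tube_hematocrit(g$vessels$diameter, h_d)
  # RBC flux in RBC/s: q [um^3/ms] * H_d / V_rbc * 1000
  rbc_flux <- abs(q) * h_d / rbc_volume * 1000
  resid <- continuity_residual(g, q)
  structure(list(node = node_ids, pressure = p,
                 vessel = g$vessels$id, q = q, h_d = h_d, h_t = h_t,
                 rbc_flux = rbc_flux, residual = resid,
                 mu = mu, mu_rel = mu_rel, conductance = cond),
            class = "mvn_flow")
}

#' @export
print.mvn_flow <- function(x, ...) {
  cat(sprintf("mvn flow field: %d vessels, |q| median %.3g um^3/ms, max continuity residual %.2e\n",
              length(x$q), stats::median(abs(x$q)), max(abs(x$residual))))
  invisible(x)
}

#' Nodal continuity residual
#'
#' Signed flow sum at every interior (non-boundary) node; zero within solver
#' tolerance for a conservative field.
#'
#' @param g an [mvn_graph()].
#' @param q signed per-vessel flows (source-to-target positive).
#' @return named vector of residuals (um^3/ms) over interior nodes.
#' @export
continuity_residual <- function(g, q) {
  n <- nrow(g$nodes)
  si <- match(g$vessels$source, g$nodes$id)
  ti <- match(g$vessels$target, g$nodes$id)
  acc <- numeric(n)
  acc_out <- tapply(q, si, sum)
  acc_in <- tapply(q, ti, sum)
  acc[as.integer(names(acc_out))] <- acc[as.integer(names(acc_out))] - unname(acc_out)
  acc[as.integer(names(acc_in))] <- acc[as.integer(names(acc_in))] + unname(acc_in)
  interior <- !g$nodes$is_boundary
  stats::setNames(acc[interior], g$nodes$id[interior])
}

#' Reynolds-number diagnostic
#'
#' Vessel Reynolds numbers `rho v D / mu` from a flow field; in the cortical
#' microvasculature these stay below 1, which justifies the Poiseuille
#' (creeping-flow) model. Reported, never enforced.
#'
#' @param g an [mvn_graph()].
#' @param flow an `mvn_flow`.
#' @param rho blood density (kg/m^3), default 1050.
#' @return numeric vector of Reynolds numbers per vessel.
#' @export
reynolds_number <- function(g, flow, rho = 1050) {
  area <- pi * g$vessels$diameter^2 / 4            # um^2
  v <- abs(flow$q) / area                           # um/ms = mm/s = 1e-3 m/s
  d_m <- g$vessels$diameter * 1e-6
  v_m <- v * 1e-3
  rho * v_m * d_m / (flow$mu * flow$mu_rel)
}

#' Fixed-point steady flow with hematocrit feedback
#'
#' Alternates the Poiseuille pressure solve with a downstream propagation of
#' discharge hematocrit through the flow-direction DAG (phase separation at
#' divergent bifurcations) until the maximum relative flow change drops
#' below `tol`. A mean-field steady companion to the discrete RBC tracker.
#'
#' @inheritParams solve_pressure_flow
#' @param tol convergence tolerance on the max relative flow change.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE`.
#' @param phase_separation `"pries"` (empirical law for parents > 10 um,
#'   flow-proportional otherwise), `"proportional"`, or `"none"` (constant
#'   hematocrit; converges in one iteration).
#' @return an `mvn_flow` with elements `converged` and `iterations`.
#' @export
fixed_point_flow_hematocrit <- function(g, bc, tol = 1e-6, max_iter = 50,
                                        mu = 1.2e-3,
                                        phase_separation = c("pries", "proportional", "none"),
                                        rbc_volume = 49) {
  phase_separation <- match.arg(phase_separation)
  h_d <- rep(bc$inflow_hematocrit, nrow(g$vessels))
  flow <- solve_pressure_flow(g, bc, h_d = h_d, mu = mu, rbc_volume = rbc_volume)
  if (phase_separation == "none") {
    flow$converged <- TRUE; flow$iterations <- 1L
    return(flow)
  }
  for (it in seq_len(max_iter)) {
    h_new <- propagate_hematocrit(g, flow, bc, phase_separation)
    flow_new <- solve_pressure_flow(g, bc, h_d = h_new, mu = mu,
                                    rbc_volume = rbc_volume)
    denom <- pmax(abs(flow$q), 1e-12)
    delta <- max(abs(flow_new$q - flow$q) / denom)
    flow <- flow_new
    if (delta < tol) {
      flow$converged <- TRUE; flow$iterations <- it + 1L
      return(flow)
    }
  }
  warning("fixed-point hematocrit iteration did not converge in ", max_iter,
          " iterations")
  flow$converged <- FALSE; flow$iterations <- max_iter + 1L
  flow
}

# steady-state downstream hematocrit propagation in topological order of the
# flow DAG; convergent nodes mix by flux, divergent nodes split RBC flux by
# the phase-separation rule
propagate_hematocrit <- function(g, flow, bc, rule, q_eps = 1e-12) {
  nv <- nrow(g$vessels)
  node_ids <- g$nodes$id
  # orient edges by flow
  from <- ifelse(flow$q >= 0, g$vessels$source, g$vessels$target)
  to <- ifelse(flow$q >= 0, g$vessels$target, g$vessels$source)
  absq <- abs(flow$q)
  active <- absq > q_eps
  # topological order over active edges
  el <- cbind(as.character(from[active]), as.character(to[active]))
  ig <- igraph::graph_from_edgelist(el, directed = TRUE)
  ord <- tryCatch(igraph::topo_sort(ig, mode = "out"),
                  error = function(e) NULL)
  if (is.null(ord)) {
    # fall back: keep hematocrit (cycle should not occur in a potential flow)
    return(flow$h_d)
  }
  ord_names <- names(ord) %||% as.character(as.integer(ord))
  h_d <- flow$h_d
  out_of <- split(which(active), from[active])
  in_of <- split(which(active), to[active])
  boundary <- g$nodes$id[g$nodes$is_boundary]
  for (nm in ord_names) {
    nid <- as.integer(nm)
    ins <- in_of[[nm]]
    outs <- out_of[[nm]]
    if (is.null(outs)) next
    if (is.null(ins)) {
      # inflow boundary node
      rbc_in <- NULL
      h_parent <- bc$inflow_hematocrit
      flux_in <- sum(absq[outs]) * h_parent
      d_parent <- NA_real_
    } else {
      flux_in <- sum(absq[ins] * h_d[ins])
      h_parent <- flux_in / max(sum(absq[ins]), q_eps)
      d_parent <- g$vessels$diameter[ins[which.max(absq[ins])]]
    }
    if (length(outs) == 1L) {
      h_d[outs] <- min(flux_in / max(absq[outs], q_eps), 0.95)
    } else if (length(outs) == 2L && rule == "pries" &&
               !is.na(d_parent) && d_parent > 10) {
      fq1 <- absq[outs[1]] / max(sum(absq[outs]), q_eps)
      fe1 <- phase_separation_fraction(fq1, d_parent,
                                       g$vessels$diameter[outs[1]],
                                       g$vessels$diameter[outs[2]],
                                       min(h_parent, 0.95))
      h_d[outs[1]] <- min(flux_in * fe1 / max(absq[outs[1]], q_eps), 0.95)
      h_d[outs[2]] <- min(flux_in * (1 - fe1) / max(absq[outs[2]], q_eps), 0.95)
    } else {
      # proportional split: daughters inherit the mixed hematocrit
      h_d[outs] <- min(h_parent, 0.95)
    }
  }
  h_d[!active] <- 0
  h_d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
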