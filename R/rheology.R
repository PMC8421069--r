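#' Empirical blood rheology laws
#'
#' In-vitro relative apparent viscosity, the Fahraeus effect (tube vs.
#' discharge hematocrit), and RBC phase separation at divergent bifurcations
#' (Pries-type empirical parameterizations). Diameters in um, hematocrits as
#' volume fractions.
#'
#' @name rheology
NULL

#' Relative effective (in-vitro) viscosity
#'
#' Ratio of the apparent blood viscosity to the plasma viscosity as a
#' function of vessel diameter and discharge hematocrit; equals 1 at
#' `h_d = 0` and reproduces the classical eta(D) curve at `h_d = 0.45`.
#'
#' @param d vessel diameter (um), > 0.
#' @param h_d discharge hematocrit in [0, 1).
#' @return dimensionless viscosity factor >= 1.
#' @export
relative_effective_viscosity <- function(d, h_d) {
  stopifnot(all(d > 0))
  if (any(h_d < 0 | h_d >= 1)) stop("discharge hematocrit must lie in [0, 1)")
  eta45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + 1 / (1 + 1e-11 * d^12)) +
    1 / (1 + 1e-11 * d^12)
  1 + (eta45 - 1) * ((1 - h_d)^cc - 1) / ((1 - 0.45)^cc - 1)
}

#' Tube hematocrit from the Fahraeus effect
#'
#' The tube (instantaneous) hematocrit is lower than the discharge
#' hematocrit because RBCs travel faster than bulk blood in narrow vessels;
#' the ratio `h_t/h_d` follows the empirical relation
#' `h_d + (1 - h_d)(1 + 1.7 exp(-0.415 D) - 0.6 exp(-0.011 D))`.
#'
#' @inheritParams relative_effective_viscosity
#' @return tube hematocrit, `<= h_d` in the microvascular range.
#' @export
fahraeus_tube_hematocrit <- function(d, h_d) {
  h_d * fahraeus_ratio(d, h_d)
}

# h_t / h_d
fahraeus_ratio <- function(d, h_d) {
  stopifnot(all(d > 0))
  if (any(h_d < 0 | h_d >= 1)) stop("discharge hematocrit must lie in [0, 1)")
  h_d + (1 - h_d) * (1 + 1.7 * exp(-0.415 * d) - 0.6 * exp(-0.011 * d))
}

# inverse: discharge hematocrit from tube hematocrit, by fixed point
fahraeus_discharge_from_tube <- function(d, h_t, iter = 30) {
  h_d <- pmin(h_t, 0.95)
  for (i in seq_len(iter)) {
    r <- fahraeus_ratio(d, pmin(h_d, 0.99))
    h_d <- pmin(h_t / pmax(r, 1e-6), 0.99)
  }
  h_d
}

#' RBC phase separation at a divergent bifurcation
#'
#' Fraction of the parent RBC flux entering daughter 1 as a function of the
#' fractional bulk blood flow into daughter 1 (`fq_b`), the parent and
#' daughter diameters, and the parent discharge hematocrit, following the
#' empirical logit law used for parent vessels wider than 10 um. Below that
#' diameter single-file flow applies and [select_daughter_single_file()] is
#' the routing rule; calling this function there is a contract error.
#'
#' @param fq_b fractional blood flow into daughter 1, in [0, 1].
#' @param d_parent,d1,d2 parent and daughter diameters (um); `d_parent` > 10.
#' @param h_d parent discharge hematocrit.
#' @return fraction of RBC flux into daughter 1, in [0, 1].
#' @export
phase_separation_fraction <- function(fq_b, d_parent, d1, d2, h_d) {
  if (any(d_parent <= 10)) {
    stop("phase separation law applies to parent diameters > 10 um; use the single-file rule")
  }
  stopifnot(all(fq_b >= 0 & fq_b <= 1))
  x0 <- 0.964 * (1 - h_d) / d_parent
  a <- -13.29 * ((d1^2 / d2^2 - 1) / (d1^2 / d2^2 + 1)) * (1 - h_d) / d_parent
  b <- 1 + 6.98 * (1 - h_d) / d_parent
  out <- numeric(length(fq_b))
  lo <- fq_b <= x0
  hi <- fq_b >= 1 - x0
  mid <- !lo & !hi
  out[lo] <- 0
  out[hi] <- 1
  if (any(mid)) {
    xr <- (fq_b[mid] - x0) / (1 - 2 * x0)
    logit <- a + b * log(xr / (1 - xr))
    out[mid] <- 1 / (1 + exp(-logit))
  }
  out
}
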