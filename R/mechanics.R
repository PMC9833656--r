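#' Virtual sample: Kelvin-Voigt or strain-stiffening specimen
#'
#' A sample is a parallel spring-dashpot (Kelvin-Voigt) with gauge length
#' `l0` and cross-section `A`. In linear mode the spring force is `k * q`;
#' in nonlinear mode the spring stress follows the strain-stiffening law
#' \eqn{\sigma(\epsilon) = (E_0/B)(e^{B\epsilon} - 1)}, whose tangent modulus
#' at zero strain is `E0` and which reduces to `E0 * eps` as `B -> 0`. The
#' dashpot contributes `c * dq/dt` in both modes. A glued soft strip cannot
#' push, so compressive spring force is clamped at zero (slack).
#'
#' @param l0 Gauge length, m.
#' @param A Cross-sectional area, m^2.
#' @param k Linear stiffness, N/m (ignored when `nonlinear` given).
#' @param c Damping, N s/m.
#' @param nonlinear Optional list `list(E0 = , B = )` with small-strain
#'   modulus `E0` (Pa) and stiffening exponent `B` (dimensionless, >= 0).
#' @return An object of class `virtual_sample`.
#' @export
#' @examples
#' virtual_sample(l0 = 8e-3, A = 2.642e-7, k = 20, c = 0.1)
virtual_sample <- function(l0, A, k = 0, c = 0, nonlinear = NULL) {
  if (l0 <= 0 || A <= 0) stop("l0 and A must be positive", call. = FALSE)
  if (k < 0 || c < 0) stop("k and c must be non-negative", call. = FALSE)
  if (!is.null(nonlinear)) {
    stopifnot(is.list(nonlinear), all(c("E0", "B") %in% names(nonlinear)))
    if (nonlinear$E0 <= 0 || nonlinear$B < 0)
      stop("nonlinear law requires E0 > 0 and B >= 0", call. = FALSE)
  }
  structure(list(l0 = l0, A = A, k = k, c = c, nonlinear = nonlinear),
            class = "virtual_sample")
}

#' @export
print.virtual_sample <- function(x, ...) {
  cat("<virtual_sample>\n")
  cat(sprintf("  l0 = %.3g mm, A = %.4g m^2\n", x$l0 * 1e3, x$A))
  if (is.null(x$nonlinear)) {
    cat(sprintf("  linear: k = %.4g N/m, c = %.4g N s/m\n", x$k, x$c))
  } else {
    cat(sprintf("  stiffening: E0 = %.4g kPa, B = %.3g, c = %.4g N s/m\n",
                x$nonlinear$E0 / 1e3, x$nonlinear$B, x$c))
  }
  invisible(x)
}

#' Strain-stiffening stress law
#'
#' \eqn{\sigma(\epsilon) = (E_0/B)(e^{B\epsilon} - 1)}; at `B = 0` the exact
#' linear limit `E0 * eps` is used.
#'
#' @param eps Engineering strain (vectorized).
#' @param E0 Small-strain tangent modulus, Pa.
#' @param B Stiffening exponent, dimensionless.
#' @return Stress in Pa.
#' @export
stiffening_stress <- function(eps, E0, B) {
  if (B == 0) return(E0 * eps)
  (E0 / B) * (exp(B * eps) - 1)
}

#' Tangent modulus of the strain-stiffening law
#'
#' @inheritParams stiffening_stress
#' @return Tangent modulus `E0 * exp(B * eps)` in Pa.
#' @export
stiffening_tangent <- function(eps, E0, B) E0 * exp(B * eps)

#' Moving-body (buoyancy cell) specification
#'
#' The bead pair and 3D-printed buoyancy cell move as one body. Total mass
#' defaults to two beads plus a 10 mg cell; the cell is neutrally buoyant so
#' gravity drops out. Drag follows the linear low-Reynolds law
#' `F_D(u) = c_d * u` with the coefficient fitted for the mounting chamber.
#'
#' @param m Total moving mass, kg. Default: two beads of `bead` plus
#'   `cell_mass`.
#' @param c_d Drag coefficient, N s/m (default 1.68e-3).
#' @param neutrally_buoyant Logical; when TRUE gravity is omitted.
#' @param bead A [bead_spec()] used for the default mass.
#' @param cell_mass Mass of the printed cell, kg (default 10 mg).
#' @return An object of class `buoyancy_cell`.
#' @export
buoyancy_cell <- function(m = NULL, c_d = 1.68e-3, neutrally_buoyant = TRUE,
                          bead = bead_spec(), cell_mass = 10e-6) {
  if (is.null(m)) m <- 2 * bead_mass(bead) + cell_mass
  if (m <= 0) stop("moving mass must be positive", call. = FALSE)
  if (c_d < 0) stop("drag coefficient must be non-negative", call. = FALSE)
  structure(list(m = m, c_d = c_d, neutrally_buoyant = neutrally_buoyant),
            class = "buoyancy_cell")
}

#' @export
print.buoyancy_cell <- function(x, ...) {
  cat(sprintf("<buoyancy_cell> m = %.4g g, c_d = %.3g N s/m%s\n",
              x$m * 1e3, x$c_d,
              if (x$neutrally_buoyant) ", neutrally buoyant" else ""))
  invisible(x)
}

#' Motion state of the moving body
#'
#' Elongation coordinate `q = x_start - x` grows as the sample stretches.
#'
#' @param q Elongation, m.
#' @param qdot Velocity, m/s.
#' @param t Time, s.
#' @return An object of class `motion_state`.
#' @export
motion_state <- function(q = 0, qdot = 0, t = 0) {
  structure(list(q = q, qdot = qdot, t = t), class = "motion_state")
}

#' Drag force on the moving body
#'
#' Linear viscous drag `-c_d * u` (opposes motion). At protocol speeds
#' (strain rates <= 0.1 s^-1 on mm-scale gauges) its magnitude is below a
#' few micronewtons and negligible next to spring forces.
#'
#' @param u Velocity, m/s (signed; vectorized).
#' @param cell A [buoyancy_cell()].
#' @return Signed drag force in N (opposite sign to `u`).
#' @export
drag_force <- function(u, cell = buoyancy_cell()) -cell$c_d * u

#' Restoring force exerted by the sample
#'
#' Kelvin-Voigt: elastic part plus `c * qdot`. The elastic part is `k * q`
#' (linear) or `A * sigma_law(q / l0)` (stiffening). A slack sample
#' (`q < 0`) exerts zero spring force; the event is flagged via attribute
#' `"slack"`.
#'
#' @param state A [motion_state()] (or list with `q`, `qdot`).
#' @param sample A [virtual_sample()].
#' @return Force in N resisting elongation, with attribute `slack`.
#' @export
restoring_force <- function(state, sample) {
  q <- state$q
  qdot <- state$qdot
  slack <- q < 0
  if (is.null(sample$nonlinear)) {
    spring <- ifelse(slack, 0, sample$k * q)
  } else {
    spring <- ifelse(slack, 0,
                     sample$A * stiffening_stress(q / sample$l0,
                                                  sample$nonlinear$E0,
                                                  sample$nonlinear$B))
  }
  out <- spring + sample$c * qdot
  attr(out, "slack") <- slack
  out
}

#' Net acceleration of the moving body
#'
#' `(F_E - restoring - drag) / m`; gravity is omitted for a neutrally
#' buoyant cell.
#'
#' @param state A [motion_state()].
#' @param F_E Applied magnetic force, N.
#' @param sample A [virtual_sample()].
#' @param cell A [buoyancy_cell()].
#' @return Acceleration in m/s^2.
#' @export
net_acceleration <- function(state, F_E, sample, cell = buoyancy_cell()) {
  if (cell$m <= 0) stop("moving mass must be positive", call. = FALSE)
  if (!all(is.finite(c(F_E, state$q, state$qdot))))
    stop("non-finite force or state", call. = FALSE)
  F_net <- F_E - as.numeric(restoring_force(state, sample)) -
    (-drag_force(state$qdot, cell))
  F_net / cell$m
}

#' Static elongation under a constant force
#'
#' Linear mode: `F / k`. Nonlinear mode: root of
#' `A * sigma_law(q / l0) = F`, by bisection to |dq| < 1e-12 m.
#'
#' @param F Applied force, N (>= 0).
#' @param sample A [virtual_sample()].
#' @return Elongation in m.
#' @export
equilibrium_elongation <- function(F, sample) {
  if (F < 0) stop("F must be non-negative", call. = FALSE)
  if (F == 0) return(0)
  if (is.null(sample$nonlinear)) {
    if (sample$k == 0)
      stop("no equilibrium: zero stiffness with non-zero force",
           call. = FALSE)
    return(F / sample$k)
  }
  g <- function(q) sample$A * stiffening_stress(q / sample$l0,
                                                sample$nonlinear$E0,
                                                sample$nonlinear$B) - F
  hi <- sample$l0
  while (g(hi) < 0) hi <- hi * 2
  lo <- 0
  # bisect to machine precision (well below the 1e-12 m contract)
  while (hi - lo > max(.Machine$double.eps * hi, 1e-18)) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
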