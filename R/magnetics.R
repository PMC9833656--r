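#' Electromagnet force-law parameters
#'
#' Constants of the exponential coil-bead pull-force law
#' \eqn{F(x, I, d) = F_0 I^2 d^3 \exp(-x/x_0)}, where `x` is the gap from the
#' magnet pole face to the center of the proximal bead. Defaults are the
#' calibrated constants of the physical actuator.
#'
#' @param F0 Force-law constant, N A^-2 m^-3.
#' @param x0 Exponential decay length of the field, m.
#' @param I_max Maximum permitted coil current, A. The ceiling exists in the
#'   hardware (driver saturation); its value is configuration.
#' @return An object of class `electromagnet_params`.
#' @export
#' @examples
#' electromagnet_params()
electromagnet_params <- function(F0 = 6.13e6, x0 = 2.258e-3, I_max = 1.0) {
  stopifnot(is.numeric(F0), is.numeric(x0), is.numeric(I_max))
  if (F0 <= 0 || x0 <= 0 || I_max <= 0)
    stop("F0, x0 and I_max must all be positive", call. = FALSE)
  structure(list(F0 = F0, x0 = x0, I_max = I_max),
            class = "electromagnet_params")
}

#' @export
print.electromagnet_params <- function(x, ...) {
  cat("<electromagnet_params>\n")
  cat(sprintf("  F0    = %.4g N A^-2 m^-3\n", x$F0))
  cat(sprintf("  x0    = %.4g m\n", x$x0))
  cat(sprintf("  I_max = %.4g A\n", x$I_max))
  invisible(x)
}

#' Ferromagnetic bead specification
#'
#' @param d Bead diameter, m. Default 6.35 mm (a standard 1/4-inch bearing
#'   ball), sized so the actuator retains several-fold force margin over the
#'   stiffest design-window sample at the 8 mm working gap.
#' @param density Bead material density, kg m^-3 (default chrome steel).
#' @return An object of class `bead_spec`.
#' @export
bead_spec <- function(d = 6.35e-3, density = 7850) {
  if (d <= 0 || density <= 0)
    stop("bead diameter and density must be positive", call. = FALSE)
  structure(list(d = d, density = density), class = "bead_spec")
}

#' @export
print.bead_spec <- function(x, ...) {
  cat(sprintf("<bead_spec> d = %.3g mm, density = %g kg/m^3, mass = %.3g g\n",
              x$d * 1e3, x$density, bead_mass(x) * 1e3))
  invisible(x)
}

#' Mass of a single bead
#'
#' @param bead A [bead_spec()].
#' @return Mass in kg.
#' @export
bead_mass <- function(bead) bead$density * pi * bead$d^3 / 6

#' Coil pull force on the proximal bead
#'
#' Evaluates \eqn{F = F_0 I^2 d^3 \exp(-x/x_0)}. The force on the distal bead
#' is modeled as exactly zero (orders of magnitude smaller). Vectorized over
#' `x` and `I`.
#'
#' @param x Gap from magnet pole face to bead center, m (>= 0).
#' @param I Coil current, A, in `[0, I_max]`.
#' @param params An [electromagnet_params()].
#' @param bead A [bead_spec()].
#' @return Force in N.
#' @export
#' @examples
#' coil_force(2.258e-3, 1, electromagnet_params(), bead_spec(d = 1e-3))
coil_force <- function(x, I, params = electromagnet_params(),
                       bead = bead_spec()) {
  if (any(x < 0)) stop("gap x must be non-negative", call. = FALSE)
  if (any(I < 0)) stop("current I must be non-negative", call. = FALSE)
  if (any(I > params$I_max))
    stop("current exceeds I_max; clamp via required_current()",
         call. = FALSE)
  params$F0 * I^2 * bead$d^3 * exp(-x / params$x0)
}

#' Current demand for a target pull force
#'
#' Analytic inverse of [coil_force()]:
#' \eqn{I = \sqrt{F / (F_0 d^3 e^{-x/x_0})}}, clamped to `[0, I_max]`.
#' Clamping is flagged rather than thrown so a control loop can continue,
#' mirroring driver saturation in hardware.
#'
#' @inheritParams coil_force
#' @param F_target Desired force, N (>= 0).
#' @return A list with `I` (A) and logical `clamped`.
#' @export
required_current <- function(F_target, x, params = electromagnet_params(),
                             bead = bead_spec()) {
  if (any(F_target < 0)) stop("F_target must be non-negative", call. = FALSE)
  if (any(x < 0)) stop("gap x must be non-negative", call. = FALSE)
  I_raw <- sqrt(F_target / (params$F0 * bead$d^3 * exp(-x / params$x0)))
  clamped <- I_raw > params$I_max
  list(I = pmin(I_raw, params$I_max), clamped = clamped)
}

#' Partial derivatives of the coil force
#'
#' Analytic partials used by the controller linearization:
#' `dF/dx = -F/x0` and `dF/dI = 2F/I` (defined as 0 at `I = 0`, the limit of
#' a force quadratic in current).
#'
#' @inheritParams coil_force
#' @return A list with `dF_dx` (N/m) and `dF_dI` (N/A).
#' @export
force_gradients <- function(x, I, params = electromagnet_params(),
                            bead = bead_spec()) {
  if (any(x < 0)) stop("gap x must be non-negative", call. = FALSE)
  if (any(I < 0)) stop("current I must be non-negative", call. = FALSE)
  F <- params$F0 * I^2 * bead$d^3 * exp(-x / params$x0)
  dF_dI <- ifelse(I > 0, 2 * F / I, 0)
  list(dF_dx = -F / params$x0, dF_dI = dF_dI)
}

#' Tabulated force surface over a gap/current grid
#'
#' The characteristic curves of the actuator: pull force over a grid of gaps
#' and currents. Exportable as delimited text for comparison with bench
#' calibration data.
#'
#' @inheritParams coil_force
#' @param x_grid Gaps, m.
#' @param I_grid Currents, A.
#' @return A tibble with columns `x_m`, `I_A`, `F_N`.
#' @export
characteristic_curves <- function(params = electromagnet_params(),
                                  bead = bead_spec(),
                                  x_grid, I_grid) {
  if (length(x_grid) == 0 || length(I_grid) == 0)
    stop("grids must be non-empty", call. = FALSE)
  grid <- expand.grid(x_m = x_grid, I_A = I_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$F_N <- coil_force(grid$x_m, grid$I_A, params, bead)
  tibble::as_tibble(grid)
}
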