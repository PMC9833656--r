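#' Closed-loop pole specification
#'
#' Target closed-loop poles of the third-order position loop: one real pole
#' and a complex-conjugate pair. Defaults are the design values of the
#' instrument: the fast real pole lets the integrator adapt quickly to the
#' unknown sample force, the complex pair sets the transient response.
#'
#' @param p1 Real pole, s^-1 (< 0).
#' @param p2_real,p2_imag Real and imaginary parts of the conjugate pair,
#'   s^-1 (`p2_real` < 0).
#' @return An object of class `pole_placement_spec`.
#' @export
pole_placement_spec <- function(p1 = -60, p2_real = -6.5, p2_imag = 1) {
  if (p1 >= 0 || p2_real >= 0)
    stop("closed-loop poles must have negative real parts", call. = FALSE)
  structure(list(p1 = p1, p2_real = p2_real, p2_imag = p2_imag),
            class = "pole_placement_spec")
}

#' Monic coefficients of the desired characteristic polynomial
#'
#' Expands `(s - p1)(s - p2)(s - p2*)` to `s^3 + a2 s^2 + a1 s + a0`.
#' For the default poles (-60, -6.5 +/- j) this is (73, 823.25, 2595).
#'
#' @param spec A [pole_placement_spec()].
#' @return Named numeric vector `c(a2, a1, a0)`.
#' @export
desired_poly_coeffs <- function(spec = pole_placement_spec()) {
  # (s^2 - 2*Re(p2) s + |p2|^2) * (s - p1)
  b1 <- -2 * spec$p2_real
  b0 <- spec$p2_real^2 + spec$p2_imag^2
  c(a2 = b1 - spec$p1,
    a1 = b0 - spec$p1 * b1,
    a0 = -spec$p1 * b0)
}

#' Linearize the plant about an operating point
#'
#' Small-signal model of bead + sample + actuator in elongation coordinates:
#' `m q'' + c_t q' + k_eff q = K_I dI`, with `F_bar = coil_force(x_bar,
#' I_bar)`, current gain `K_I = 2 F_bar / I_bar` and effective stiffness
#' `k_eff = k_hat - F_bar / x0`. The exponential force law contributes a
#' destabilizing stiffness `+F_bar/x0` in elongation coordinates, so `k_eff`
#' may be negative at high force (magnetic destabilization).
#'
#' @param x_bar Operating gap, m.
#' @param I_bar Operating current, A (`K_I = 0` when zero).
#' @param k_hat Sample stiffness estimate, N/m.
#' @param c_hat Sample damping estimate, N s/m.
#' @param cell A [buoyancy_cell()].
#' @param params An [electromagnet_params()].
#' @param bead A [bead_spec()].
#' @return An object of class `plant_linearization` with fields `m`, `c_t`,
#'   `k_eff`, `K_I`, `F_bar`, `I_bar`.
#' @export
linearize_plant <- function(x_bar, I_bar, k_hat = 0, c_hat = 0,
                            cell = buoyancy_cell(),
                            params = electromagnet_params(),
                            bead = bead_spec()) {
  if (x_bar < 0) stop("gap must be non-negative", call. = FALSE)
  F_bar <- if (I_bar > 0) coil_force(x_bar, min(I_bar, params$I_max),
                                     params, bead) else 0
  K_I <- if (I_bar > 0) 2 * F_bar / I_bar else 0
  structure(list(m = cell$m,
                 c_t = c_hat + cell$c_d,
                 k_eff = k_hat - F_bar / params$x0,
                 K_I = K_I, F_bar = F_bar, I_bar = I_bar),
            class = "plant_linearization")
}

#' PID gains container
#'
#' @param Kp Proportional gain, A/m.
#' @param Ki Integral gain, A m^-1 s^-1 (already limited to `Ki_max`).
#' @param Kd Derivative gain, A s/m.
#' @param Ki_max Integral-gain ceiling applied during placement.
#' @param I_clamp Clamp on the integral term's output, A.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(Kp, Ki, Kd, Ki_max = Inf, I_clamp = Inf) {
  stopifnot(all(is.finite(c(Kp, Ki, Kd))))
  structure(list(Kp = Kp, Ki = Ki, Kd = Kd,
                 Ki_max = Ki_max, I_clamp = I_clamp),
            class = "pid_gains")
}

#' @export
print.pid_gains <- function(x, ...) {
  cat(sprintf("<pid_gains> Kp = %.5g A/m, Ki = %.5g A/(m s), Kd = %.5g A s/m\n",
              x$Kp, x$Ki, x$Kd))
  invisible(x)
}

#' Pole-placement PID gains for the linearized plant
#'
#' Matches the closed-loop characteristic polynomial
#' `m s^3 + (c_t + K_I Kd) s^2 + (k_eff + K_I Kp) s + K_I Ki`
#' to `m (s - p1)(s - p2)(s - p2*)`:
#' `Kd = (m a2 - c_t)/K_I`, `Kp = (m a1 - k_eff)/K_I`, `Ki = m a0 / K_I`,
#' then limits `Ki` to `Ki_max` (wind-up protection for highly damped
#' samples).
#'
#' @param lin A [linearize_plant()] result with `K_I > 0`.
#' @param spec A [pole_placement_spec()].
#' @param Ki_max Integral-gain ceiling, A m^-1 s^-1.
#' @param I_clamp Integral-output clamp carried into the gain set, A.
#' @return A [pid_gains()].
#' @export
place_poles <- function(lin, spec = pole_placement_spec(), Ki_max = Inf,
                        I_clamp = Inf) {
  if (lin$K_I <= 0)
    stop("plant is not actuatable (K_I <= 0); use bootstrap gains",
         call. = FALSE)
  a <- desired_poly_coeffs(spec)
  pid_gains(Kp = (lin$m * a[["a1"]] - lin$k_eff) / lin$K_I,
            Ki = min(lin$m * a[["a0"]] / lin$K_I, Ki_max),
            Kd = (lin$m * a[["a2"]] - lin$c_t) / lin$K_I,
            Ki_max = Ki_max, I_clamp = I_clamp)
}

#' Controller configuration
#'
#' All tunables of the adaptive PID loop. Defaults mirror the instrument:
#' control at the 200 Hz CCD frame rate, current ceiling `I_max` from the
#' magnet parameters, conditional-integration anti-windup, online secant
#' stiffness estimate clamped to `[0, k_hat_max]`, and a small initial bias
#' current (a low current is applied first in hardware to align the
#' specimen), which also bootstraps the adaptive linearization.
#'
#' @param poles A [pole_placement_spec()].
#' @param Ki_max Integral-gain ceiling, A m^-1 s^-1.
#' @param I_max Current ceiling, A (defaults to the magnet's).
#' @param I_clamp Integral-term output clamp, A (default `I_max`).
#' @param bootstrap [pid_gains()] used while the operating current is zero.
#' @param k_hat_max Upper clamp on the secant stiffness estimate, N/m.
#' @param q_min Elongation below which the stiffness estimate falls back to
#'   zero, m (guards the secant against sensor noise near zero stretch).
#' @param c_hat Sample damping estimate used in the linearization, N s/m
#'   (0: unknown in hardware; extra true damping only adds margin).
#' @param I_init Initial bias current, A.
#' @param I_op_min Floor on the operating current used by the adaptive
#'   linearization, A (default `I_init`). Below it the modeled current gain
#'   is held at its floor value, which bounds the recomputed gains as the
#'   commanded current approaches zero; the modeled loop gain then exceeds
#'   the physical one, which only adds gain margin.
#' @param deriv_tau First-order filter time constant on the derivative
#'   term, s (default 5 ms, one control period; bounds the noise amplified
#'   by the derivative gain while keeping the extra phase lag at the plant
#'   resonance small).
#' @param k_hat_tau First-order filter time constant on the stiffness
#'   estimate, s (default 0.5 s). The raw secant estimate follows the
#'   loop's own transients and closes a parametric feedback path that can
#'   pump oscillations at high sample stiffness; filtering it an order of
#'   magnitude slower than the placed poles decouples parameter adaptation
#'   from the position dynamics, as is standard for online estimators.
#' @param dt Control period, s (one CCD frame).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(poles = pole_placement_spec(),
                              Ki_max = 5e4,
                              I_max = 1.0,
                              I_clamp = I_max,
                              bootstrap = pid_gains(Kp = 50, Ki = 500, Kd = 0),
                              k_hat_max = 100,
                              q_min = 2e-5,
                              c_hat = 0,
                              I_init = 0.02,
                              I_op_min = I_init,
                              deriv_tau = 0.005,
                              k_hat_tau = 0.5,
                              dt = 1 / 200) {
  stopifnot(inherits(poles, "pole_placement_spec"),
            inherits(bootstrap, "pid_gains"),
            Ki_max > 0, I_max > 0, I_clamp > 0, dt > 0,
            k_hat_max > 0, q_min >= 0, c_hat >= 0, I_init >= 0,
            I_op_min >= 0, deriv_tau >= 0, k_hat_tau >= 0)
  structure(list(poles = poles, Ki_max = Ki_max, I_max = I_max,
                 I_clamp = I_clamp, bootstrap = bootstrap,
                 k_hat_max = k_hat_max, q_min = q_min, c_hat = c_hat,
                 I_init = I_init, I_op_min = I_op_min,
                 deriv_tau = deriv_tau, k_hat_tau = k_hat_tau, dt = dt),
            class = "controller_config")
}

#' Secant stiffness estimate
#'
#' `k_hat = F_bar / q_bar`, clamped to `[0, k_hat_max]`; returns 0 before
#' motion begins (`q_bar < q_min`). In the closed loop `q_bar` is the
#' commanded reference elongation and the result is first-order filtered
#' with time constant `k_hat_tau` (see [adaptive_update()]).
#'
#' @param F_bar Operating force, N.
#' @param q_bar Measured elongation, m.
#' @param config A [controller_config()].
#' @return Stiffness estimate in N/m.
#' @export
estimate_stiffness <- function(F_bar, q_bar, config = controller_config()) {
  if (!is.finite(q_bar) || q_bar < config$q_min) return(0)
  min(max(F_bar / q_bar, 0), config$k_hat_max)
}

#' One adaptive gain update
#'
#' Composes [linearize_plant()] and [place_poles()] at the current measured
#' operating point (gap `x`, current `I`), recomputing the gains so the
#' frozen-time closed-loop poles stay at the specification at every step.
#' The operating current is floored at `I_op_min` so the recomputed gains
#' stay bounded and continuous as the command approaches zero; if both the
#' measured current and the floor are zero the plant is not actuatable and
#' the configured bootstrap gains are returned.
#'
#' @param x Measured gap, m.
#' @param I Measured coil current, A.
#' @param q Elongation used for the secant stiffness estimate, m. The
#'   closed-loop runner passes the commanded reference here rather than the
#'   fed-back measurement: dividing by the measurement makes the estimate's
#'   sensitivity to it of order F/q^2, which (multiplied by the steady
#'   tracking error) closes a destabilizing parametric loop on stiff
#'   samples.
#' @param config A [controller_config()].
#' @param cell A [buoyancy_cell()].
#' @param params An [electromagnet_params()].
#' @param bead A [bead_spec()].
#' @param k_hat Optional externally maintained (filtered) stiffness
#'   estimate, N/m; when NULL the instantaneous secant estimate is used.
#'   The closed-loop runner maintains the filtered estimate (time constant
#'   `k_hat_tau`) and passes it here.
#' @return A [pid_gains()].
#' @export
adaptive_update <- function(x, I, q, config = controller_config(),
                            cell = buoyancy_cell(),
                            params = electromagnet_params(),
                            bead = bead_spec(), k_hat = NULL) {
  I_lin <- max(I, config$I_op_min)
  if (I_lin <= 0) {
    g <- config$bootstrap
    g$Ki_max <- config$Ki_max
    g$I_clamp <- config$I_clamp
    return(g)
  }
  F_bar <- coil_force(x, min(I_lin, params$I_max), params, bead)
  if (is.null(k_hat)) k_hat <- estimate_stiffness(F_bar, q, config)
  lin <- linearize_plant(x, I_lin, k_hat = k_hat, c_hat = config$c_hat,
                         cell = cell, params = params, bead = bead)
  place_poles(lin, config$poles, Ki_max = config$Ki_max,
              I_clamp = config$I_clamp)
}

#' Fresh controller state
#'
#' @return An object of class `controller_state` holding the integral
#'   accumulator (A), the previous measurement (m), previous error (m) and
#'   the filtered derivative (m/s).
#' @export
controller_state <- function(integral = 0, prev_meas = NA_real_,
                             prev_error = 0, deriv_f = 0) {
  structure(list(integral = integral, prev_meas = prev_meas,
                 prev_error = prev_error, deriv_f = deriv_f),
            class = "controller_state")
}

#' One discrete PID step
#'
#' `e = reference - measurement`; output = `Kp e + integral +
#' Kd * d(-measurement)/dt` (derivative on measurement, avoiding setpoint
#' kick; first-order filtered with time constant `deriv_tau` to bound
#' sensor-noise amplification). The integral advances trapezoidally and is
#' (a) clamped to `+/- I_clamp` and (b) frozen while the output is
#' saturated at 0 or `I_max` in the direction the error would push further
#' (conditional integration). The output is clamped to `[0, I_max]`.
#'
#' @param reference Reference position (elongation), m.
#' @param measurement Measured position, m.
#' @param gains A [pid_gains()].
#' @param state A [controller_state()].
#' @param dt Step, s.
#' @param I_max Current ceiling, A.
#' @param deriv_tau Derivative filter time constant, s (0 = unfiltered).
#' @return List with `I` (commanded current, A), `saturated` (logical) and
#'   the advanced `state`.
#' @export
pid_step <- function(reference, measurement, gains, state, dt,
                     I_max = 1.0, deriv_tau = 0) {
  if (!all(is.finite(c(reference, measurement, dt))) || dt <= 0)
    stop("controller fault: non-finite input or bad dt", call. = FALSE)
  e <- reference - measurement
  deriv_raw <- if (is.na(state$prev_meas)) 0 else
    -(measurement - state$prev_meas) / dt
  beta <- deriv_tau / (deriv_tau + dt)
  deriv <- beta * state$deriv_f + (1 - beta) * deriv_raw
  clamp <- min(gains$I_clamp, Inf)
  integ_new <- state$integral + gains$Ki * (e + state$prev_error) / 2 * dt
  integ_new <- max(min(integ_new, clamp), -clamp)
  u_raw <- gains$Kp * e + integ_new + gains$Kd * deriv
  u <- max(min(u_raw, I_max), 0)
  saturated <- u_raw > I_max || u_raw < 0
  # conditional integration: keep the old accumulator if integrating would
  # push further into the active saturation
  if ((u_raw > I_max && e > 0) || (u_raw < 0 && e < 0)) {
    integ_new <- state$integral
  }
  list(I = u, saturated = saturated,
       state = controller_state(integral = integ_new,
                                prev_meas = measurement,
                                prev_error = e, deriv_f = deriv))
}

#' Roots of the closed-loop characteristic polynomial
#'
#' Diagnostic used to verify pole invariance: builds
#' `m s^3 + (c_t + K_I Kd) s^2 + (k_eff + K_I Kp) s + K_I Ki` from a plant
#' linearization and a gain set and returns its roots.
#'
#' @param lin A [linearize_plant()] result.
#' @param gains A [pid_gains()].
#' @return Complex vector of the three closed-loop poles.
#' @export
closed_loop_poles <- function(lin, gains) {
  polyroot(c(lin$K_I * gains$Ki,
             lin$k_eff + lin$K_I * gains$Kp,
             lin$c_t + lin$K_I * gains$Kd,
             lin$m))
}
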