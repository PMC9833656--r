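#' Reference motion program
#'
#' Reference elongation-vs-time programs for the control loop, expressed as
#' position (elongation) like the instrument's prescribed reference signals;
#' strain protocols are converted through the gauge length `l0`.
#'
#' * `ramp`: `q(t) = l0 * strain_rate * t`, capped at `l0 * target_strain`.
#' * `triangle`: up then down at the same rate, then zero.
#' * `cycles`: `n_cycles` concatenated triangles.
#' * `hold`: constant `l0 * target_strain`.
#'
#' @param kind One of `"ramp"`, `"triangle"`, `"cycles"`, `"hold"`.
#' @param strain_rate Strain rate, s^-1 (> 0 for moving kinds).
#' @param target_strain Peak strain, dimensionless.
#' @param n_cycles Number of cycles (cyclic kinds).
#' @param l0 Gauge length, m.
#' @return An object of class `reference_signal`.
#' @export
#' @examples
#' r <- make_reference("ramp", strain_rate = 0.025, target_strain = 0.6,
#'                     l0 = 8e-3)
#' sample_reference(r, 24)  # 4.8e-3 m
make_reference <- function(kind = c("ramp", "triangle", "cycles", "hold"),
                           strain_rate = 2e-3, target_strain = 0.1,
                           n_cycles = 1, l0 = 8e-3) {
  kind <- match.arg(kind)
  if (kind != "hold" && strain_rate <= 0)
    stop("strain_rate must be positive for moving programs", call. = FALSE)
  if (target_strain <= 0 && kind != "hold")
    stop("target_strain must be positive", call. = FALSE)
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  structure(list(kind = kind, strain_rate = strain_rate,
                 target_strain = target_strain,
                 n_cycles = as.integer(n_cycles), l0 = l0),
            class = "reference_signal")
}

#' Sample a reference program at given times
#'
#' @param ref A [make_reference()] program.
#' @param t Times, s (vectorized).
#' @return Reference elongations, m.
#' @export
sample_reference <- function(ref, t) {
  q_max <- ref$l0 * ref$target_strain
  v <- ref$l0 * ref$strain_rate
  switch(ref$kind,
    ramp = pmin(v * t, q_max),
    hold = rep(q_max, length(t)),
    triangle = {
      T_up <- q_max / v
      q <- ifelse(t <= T_up, v * t, 2 * q_max - v * t)
      pmax(0, pmin(q, q_max))
    },
    cycles = {
      period <- 2 * q_max / v
      tt <- t
      done <- tt >= ref$n_cycles * period
      tc <- tt %% period
      q <- ifelse(tc <= period / 2, v * tc, 2 * q_max - v * tc)
      ifelse(done, 0, pmax(0, pmin(q, q_max)))
    })
}

#' Natural duration of a reference program, s
#' @param ref A [make_reference()] program.
#' @export
reference_duration <- function(ref) {
  q_max <- ref$l0 * ref$target_strain
  v <- ref$l0 * ref$strain_rate
  switch(ref$kind,
    ramp = q_max / v,
    hold = 0,
    triangle = 2 * q_max / v,
    cycles = ref$n_cycles * 2 * q_max / v)
}

#' Run the closed-loop digital twin
#'
#' Integrates the full instrument loop: at each 200 Hz control tick the CCD
#' model renders and localizes the bead shadow (noise, quantization, frame
#' delay), the adaptive PID recomputes its gains at the measured operating
#' point and issues a current command, and the bead/sample mechanics are
#' advanced by fixed-substep RK4 under zero-order-hold current. Bit-for-bit
#' reproducible under a fixed seed.
#'
#' @param sample A [virtual_sample()].
#' @param reference A [make_reference()] program.
#' @param duration Simulated time, s (default: program duration + 10 s
#'   settle).
#' @param seed Integer seed for the sensor noise stream.
#' @param cell A [buoyancy_cell()].
#' @param magnet An [electromagnet_params()].
#' @param bead A [bead_spec()].
#' @param ccd A [ccd_config()].
#' @param controller A [controller_config()].
#' @param x_start Initial magnet-face-to-bead gap, m (default 8 mm, the
#'   working gap of the instrument).
#' @param n_sub RK4 substeps per control tick (default 10, i.e. 0.5 ms
#'   steps, well below the ~1/60 s closed-loop time constants).
#' @return An object of class `simulation_trace`: a per-tick tibble
#'   (`t_s`, `q_ref_m`, `q_true_m`, `q_meas_m`, `I_A`, `F_E_N`,
#'   `F_spring_N`, `F_drag_N`, gain snapshots, `flags`) plus configuration
#'   metadata. Flag bits: 1 current saturated, 2 measurement dropped,
#'   4 slack sample.
#' @export
run_closed_loop <- function(sample, reference, duration = NULL, seed = 1,
                            cell = buoyancy_cell(),
                            magnet = electromagnet_params(),
                            bead = bead_spec(),
                            ccd = ccd_config(),
                            controller = controller_config(),
                            x_start = 8e-3, n_sub = 10) {
  stopifnot(inherits(sample, "virtual_sample"),
            inherits(reference, "reference_signal"))
  if (is.null(duration)) duration <- reference_duration(reference) + 10
  N <- max(2L, as.integer(floor(duration * ccd$frame_rate)))
  tt <- (seq_len(N) - 1) / ccd$frame_rate
  q_ref <- sample_reference(reference, tt)

  nl <- !is.null(sample$nonlinear)
  plant_cfg <- list(F0 = magnet$F0, x0 = magnet$x0, d = bead$d,
                    l0 = sample$l0, A = sample$A, k = sample$k,
                    c = sample$c, nonlinear = nl,
                    E0 = if (nl) sample$nonlinear$E0 else 0,
                    B = if (nl) sample$nonlinear$B else 0,
                    m = cell$m, c_d = cell$c_d, x_start = x_start)
  s0 <- ccd$n_pixels * ccd$pitch / (2 * ccd$magnification)
  sensor_cfg <- list(n_pixels = ccd$n_pixels, pitch = ccd$pitch,
                     adc_bits = ccd$adc_bits,
                     magnification = ccd$magnification,
                     noise_sd = ccd$noise_sd,
                     delay_frames = ccd$delay_frames,
                     bright_level = ccd$bright_level,
                     dark_level = ccd$dark_level, s0 = s0)
  a <- desired_poly_coeffs(controller$poles)
  I_max <- min(controller$I_max, magnet$I_max)
  ctrl_cfg <- list(a2 = a[["a2"]], a1 = a[["a1"]], a0 = a[["a0"]],
                   Ki_max = controller$Ki_max, I_max = I_max,
                   I_clamp = controller$I_clamp,
                   bKp = controller$bootstrap$Kp,
                   bKi = controller$bootstrap$Ki,
                   bKd = controller$bootstrap$Kd,
                   k_hat_max = controller$k_hat_max,
                   q_min = controller$q_min, c_hat = controller$c_hat,
                   I_op_min = controller$I_op_min,
                   deriv_tau = controller$deriv_tau,
                   k_hat_tau = controller$k_hat_tau,
                   dt = 1 / ccd$frame_rate)

  set.seed(seed)
  out <- .run_closed_loop_core(q_ref, plant_cfg, sensor_cfg, ctrl_cfg,
                               controller$I_init, as.integer(n_sub))
  n_done <- length(out$t_s)
  data <- tibble::tibble(t_s = out$t_s, q_ref_m = q_ref[seq_len(n_done)],
                         q_true_m = out$q_true_m, q_meas_m = out$q_meas_m,
                         I_A = out$I_A, F_E_N = out$F_E_N,
                         F_spring_N = out$F_spring_N,
                         F_drag_N = out$F_drag_N,
                         Kp = out$Kp, Ki = out$Ki, Kd = out$Kd,
                         k_hat = out$k_hat, flags = out$flags)
  trace <- structure(list(data = data, sample = sample, cell = cell,
                          magnet = magnet, bead = bead, ccd = ccd,
                          controller = controller, reference = reference,
                          x_start = x_start, seed = seed, n_sub = n_sub),
                     class = "simulation_trace")
  if (out$status != 0) {
    cnd <- structure(class = c("tensiletwin_instability", "error",
                               "condition"),
                     list(message = sprintf(
                       "numerical blow-up at t = %.3f s (|q| > 10 l0); trace prefix attached",
                       data$t_s[n_done]), call = NULL, trace = trace))
    stop(cnd)
  }
  trace
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat(sprintf("<simulation_trace> %d ticks (%.3g s at %g Hz), seed %d\n",
              nrow(x$data), max(x$data$t_s), x$ccd$frame_rate, x$seed))
  cat(sprintf("  reference: %s, rate %.3g /s, target strain %.3g\n",
              x$reference$kind, x$reference$strain_rate,
              x$reference$target_strain))
  cat(sprintf("  max |q_meas - q_ref| = %.3g m (%.2f%% of span)\n",
              max(abs(x$data$q_meas_m - x$data$q_ref_m)),
              100 * tracking_error(x)))
  invisible(x)
}

#' Maximum relative tracking error of a trace
#'
#' `max |measured - reference| / (commanded displacement span)` over the
#' whole trace, including the initial transient.
#'
#' @param trace A [run_closed_loop()] trace.
#' @return Dimensionless error (fraction of the commanded span).
#' @export
tracking_error <- function(trace) {
  span <- diff(range(trace$data$q_ref_m))
  if (span == 0) span <- trace$reference$l0 * trace$reference$target_strain
  max(abs(trace$data$q_meas_m - trace$data$q_ref_m)) / span
}

#' Validation protocol: slow ramp to 10% strain
#'
#' Convenience wrapper reproducing the controller validation test: a ramp
#' reference at strain rate 2e-3 s^-1 up to 10% strain with the default
#' sensor/controller, followed by a settle period. Returns the trace with a
#' `summary` element holding the maximum relative tracking error.
#'
#' @inheritParams run_closed_loop
#' @param strain_rate Ramp strain rate, s^-1.
#' @param target_strain Peak strain.
#' @param settle Extra time after the ramp, s.
#' @return A `simulation_trace` with an added `summary` list
#'   (`max_rel_error`).
#' @export
run_validation_protocol <- function(sample, strain_rate = 2e-3,
                                    target_strain = 0.10, settle = 10,
                                    seed = 1, ...) {
  ref <- make_reference("ramp", strain_rate = strain_rate,
                        target_strain = target_strain, l0 = sample$l0)
  trace <- run_closed_loop(sample, ref,
                           duration = reference_duration(ref) + settle,
                           seed = seed, ...)
  trace$summary <- list(max_rel_error = tracking_error(trace))
  trace
}

#' Run a suite of motion protocols on one sample
#'
#' One closed-loop trace per protocol (e.g. six-cycle preconditioning,
#' ramps at the three tissue strain rates, a triangular hysteresis cycle).
#' Each protocol gets a distinct seed derived from `seed`.
#'
#' @param sample A [virtual_sample()].
#' @param protocols Named list of [make_reference()] programs.
#' @param seed Base seed; protocol `i` uses `seed + i - 1`.
#' @param ... Passed to [run_closed_loop()].
#' @return Named list of `simulation_trace` objects.
#' @export
run_protocol_suite <- function(sample, protocols, seed = 1, ...) {
  if (length(protocols) == 0) return(list())
  out <- vector("list", length(protocols))
  names(out) <- names(protocols)
  for (i in seq_along(protocols)) {
    out[[i]] <- run_closed_loop(sample, protocols[[i]],
                                duration = reference_duration(protocols[[i]]) + 5,
                                seed = seed + i - 1, ...)
  }
  out
}
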