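#' Engineering stress-strain curve
#'
#' Paired engineering strain/stress arrays with geometry provenance.
#'
#' @param strain Dimensionless strain array (>= -1).
#' @param stress Stress array, Pa.
#' @param A Cross-sectional area, m^2.
#' @param l0 Gauge length, m.
#' @param monotone_loading Logical flag: strain is monotone non-decreasing.
#' @return An object of class `stress_strain_curve`.
#' @export
stress_strain_curve <- function(strain, stress, A, l0,
                                monotone_loading = !is.unsorted(strain)) {
  if (length(strain) != length(stress))
    stop("strain and stress must have equal length", call. = FALSE)
  if (any(strain < -1)) stop("strain below -1 is unphysical", call. = FALSE)
  if (!all(is.finite(stress))) stop("stress must be finite", call. = FALSE)
  structure(list(strain = strain, stress = stress, A = A, l0 = l0,
                 monotone_loading = isTRUE(monotone_loading)),
            class = "stress_strain_curve")
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf(
    "<stress_strain_curve> %d points, strain [%.4g, %.4g], stress [%.4g, %.4g] Pa\n",
    length(x$strain), min(x$strain), max(x$strain),
    min(x$stress), max(x$stress)))
  invisible(x)
}

#' Convert force/elongation records to engineering stress-strain
#'
#' `sigma_i = F_i / A`, `eps_i = q_i / l0`.
#'
#' @param force Forces, N.
#' @param elongation Elongations `q = l - l0`, m.
#' @param A Cross-sectional area, m^2 (> 0).
#' @param l0 Gauge length, m (> 0).
#' @return A [stress_strain_curve()].
#' @export
to_stress_strain <- function(force, elongation, A, l0) {
  if (A <= 0 || l0 <= 0)
    stop("geometry (A, l0) must be positive", call. = FALSE)
  if (length(force) != length(elongation))
    stop("force and elongation must have equal length", call. = FALSE)
  stress_strain_curve(elongation / l0, force / A, A = A, l0 = l0)
}

#' Stress-strain curve from a simulation trace
#'
#' Matches the instrument's analysis chain: the tensile force is the coil
#' force law evaluated at the *measured* gap and current (the device has no
#' load cell), and strain uses the measured elongation. Drag is negligible
#' at protocol speeds and not subtracted by default.
#'
#' @param trace A [run_closed_loop()] trace.
#' @param use_measured Use measured elongation/current (default) or the true
#'   state.
#' @param subtract_drag Subtract the modeled drag force from the tensile
#'   force (optional correction; default FALSE).
#' @return A [stress_strain_curve()].
#' @export
trace_to_curve <- function(trace, use_measured = TRUE,
                           subtract_drag = FALSE) {
  d <- trace$data
  q <- if (use_measured) d$q_meas_m else d$q_true_m
  x <- pmax(0, trace$x_start - q)
  F <- coil_force(x, d$I_A, trace$magnet, trace$bead)
  if (subtract_drag) F <- F + d$F_drag_N  # F_drag is signed against motion
  to_stress_strain(F, q, trace$sample$A, trace$sample$l0)
}

#' Windowed Young's modulus
#'
#' Ordinary least-squares slope of stress on strain restricted to a closed
#' strain window (an intercept absorbs any pre-tension offset, so it does
#' not bias the slope).
#'
#' @param curve A [stress_strain_curve()].
#' @param window Closed strain interval `c(lo, hi)`; boundary points are
#'   included. Default is the 5-10% region used for the elastomer
#'   validation.
#' @return An object of class `modulus_estimate`: `E` (Pa), `window`,
#'   `residual` (residual standard deviation, Pa), `n`.
#' @export
youngs_modulus <- function(curve, window = c(0.05, 0.10)) {
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be c(lo, hi) with lo < hi", call. = FALSE)
  in_win <- curve$strain >= window[1] & curve$strain <= window[2]
  if (sum(in_win) < 3)
    stop(sprintf("window error: only %d point(s) in [%g, %g]",
                 sum(in_win), window[1], window[2]), call. = FALSE)
  fit <- stats::lm(stress ~ strain,
                   data = data.frame(strain = curve$strain[in_win],
                                     stress = curve$stress[in_win]))
  n <- sum(in_win)
  structure(list(E = unname(stats::coef(fit)[2]), window = window,
                 residual = sqrt(sum(stats::residuals(fit)^2) / (n - 2)),
                 n = n),
            class = "modulus_estimate")
}

#' @export
print.modulus_estimate <- function(x, ...) {
  cat(sprintf(
    "<modulus_estimate> E = %.4g kPa in window [%g, %g] (n = %d, resid sd = %.3g Pa)\n",
    x$E / 1e3, x$window[1], x$window[2], x$n, x$residual))
  invisible(x)
}

#' Split a cyclic curve into loading and unloading branches
#'
#' Splits at the strain maximum (the turning point of a triangle protocol).
#'
#' @param curve A [stress_strain_curve()].
#' @return List with `loading` and `unloading` curves (the peak point is
#'   shared).
#' @export
split_loading_unloading <- function(curve) {
  i_peak <- which.max(curve$strain)
  idx_l <- seq_len(i_peak)
  idx_u <- seq(i_peak, length(curve$strain))
  list(loading = stress_strain_curve(curve$strain[idx_l],
                                     curve$stress[idx_l],
                                     curve$A, curve$l0),
       unloading = stress_strain_curve(curve$strain[idx_u],
                                       curve$stress[idx_u],
                                       curve$A, curve$l0))
}

#' Hysteresis metrics of a loading/unloading cycle
#'
#' The loop area is the integral of (loading stress - unloading stress)
#' over the strain interval shared by both branches (each branch is
#' interpolated onto a common grid, which makes the metric insensitive to
#' the branches ending at slightly different strains, as measured branches
#' under tracking lag do). The dissipation ratio divides the loop area by
#' the area under the loading branch over the same interval. Windowed
#' moduli are fitted per branch.
#'
#' @param loading,unloading [stress_strain_curve()] branches spanning a
#'   shared strain interval.
#' @param windows List of strain windows for per-branch moduli (default the
#'   low- and high-strain windows 0-10% and 50-60%).
#' @param n_grid Interpolation grid size.
#' @return List with `loop_area` (Pa), `dissipation_ratio`, the shared
#'   strain `overlap`, and a tibble `moduli` (window, E_load, E_unload in
#'   Pa). Window fits that lack points are returned as NA.
#' @export
hysteresis_metrics <- function(loading, unloading,
                               windows = list(c(0, 0.10), c(0.50, 0.60)),
                               n_grid = 512) {
  lo <- max(min(loading$strain), min(unloading$strain))
  hi <- min(max(loading$strain), max(unloading$strain))
  if (hi <= lo)
    stop("branches do not overlap in strain", call. = FALSE)
  grid <- seq(lo, hi, length.out = n_grid)
  interp <- function(curve) {
    stats::approx(curve$strain, curve$stress, xout = grid,
                  ties = mean)$y
  }
  sig_l <- interp(loading)
  sig_u <- interp(unloading)
  dg <- grid[2] - grid[1]
  trap <- function(y) sum((utils::head(y, -1) + utils::tail(y, -1)) / 2) * dg
  loop_area <- trap(sig_l - sig_u)
  load_area <- trap(sig_l)
  fit_safe <- function(curve, w) {
    tryCatch(youngs_modulus(curve, w)$E, error = function(e) NA_real_)
  }
  moduli <- tibble::tibble(
    window_lo = vapply(windows, `[`, numeric(1), 1),
    window_hi = vapply(windows, `[`, numeric(1), 2),
    E_load = vapply(windows, fit_safe, numeric(1), curve = loading),
    E_unload = vapply(windows, fit_safe, numeric(1), curve = unloading))
  list(loop_area = loop_area,
       dissipation_ratio = loop_area / load_area,
       overlap = c(lo, hi),
       moduli = moduli)
}

#' Cycle-to-cycle preconditioning deviations
#'
#' Relative changes of the per-cycle maximum strain:
#' `dev_i = |eps_max_i - eps_max_{i-1}| / eps_max_{i-1}` for `i >= 2`.
#'
#' @param maxima Per-cycle maximum strains (>= 2 cycles, all > 0).
#' @return Vector of length `length(maxima) - 1`.
#' @export
#' @examples
#' preconditioning_deviation(c(0.50, 0.53, 0.545, 0.55))
preconditioning_deviation <- function(maxima) {
  if (length(maxima) < 2)
    stop("need at least two cycle maxima", call. = FALSE)
  if (any(maxima == 0)) stop("zero cycle maxima", call. = FALSE)
  abs(diff(maxima)) / utils::head(maxima, -1)
}

#' First cycle after which preconditioning deviations stay below a threshold
#'
#' @param maxima Per-cycle maximum strains.
#' @param threshold Relative deviation threshold (default 5%).
#' @return The 1-based cycle index `i` such that the deviation from cycle
#'   `i` to `i + 1` (and all later ones) is below the threshold; `NA` if
#'   never reached.
#' @export
preconditioning_converged_after <- function(maxima, threshold = 0.05) {
  dev <- preconditioning_deviation(maxima)
  below <- rev(cumprod(rev(dev < threshold))) == 1
  if (!any(below)) return(NA_integer_)
  which(below)[1] + 1L
}

#' Per-cycle maximum measured strain of a cyclic trace
#'
#' Cycles are delimited by the reference program's period; the maximum of
#' the measured strain within each cycle is returned.
#'
#' @param trace A trace driven by a `cycles` (or `triangle`) reference.
#' @return Numeric vector of per-cycle maximum strains.
#' @export
cycle_maxima <- function(trace) {
  ref <- trace$reference
  if (!ref$kind %in% c("cycles", "triangle"))
    stop("trace was not driven by a cyclic reference", call. = FALSE)
  period <- 2 * ref$target_strain / ref$strain_rate
  n_cyc <- if (ref$kind == "cycles") ref$n_cycles else 1L
  eps <- trace$data$q_meas_m / trace$sample$l0
  idx <- pmin(floor(trace$data$t_s / period), n_cyc - 1)
  keep <- trace$data$t_s < n_cyc * period
  vapply(split(eps[keep], idx[keep]), max, numeric(1), USE.NAMES = FALSE)
}

#' Young's modulus per strain rate and window
#'
#' Tidy summary table for strain-rate studies: one windowed modulus fit per
#' (trace, window) pair.
#'
#' @param traces List of traces (or `stress_strain_curve`s), one per rate.
#' @param rates Strain rates, s^-1 (default: taken from each trace's
#'   reference program).
#' @param windows List of strain windows (default 0-10% and 50-60%).
#' @param ... Passed to [trace_to_curve()] when traces are given.
#' @return A tibble with `rate`, `window_lo`, `window_hi`, `E`, `residual`,
#'   `n`.
#' @export
strain_rate_summary <- function(traces, rates = NULL,
                                windows = list(c(0, 0.10), c(0.50, 0.60)),
                                ...) {
  curves <- lapply(traces, function(tr) {
    if (inherits(tr, "simulation_trace")) trace_to_curve(tr, ...) else tr
  })
  if (is.null(rates)) {
    rates <- vapply(traces, function(tr) {
      if (inherits(tr, "simulation_trace")) tr$reference$strain_rate
      else NA_real_
    }, numeric(1))
  }
  rows <- list()
  for (i in seq_along(curves)) {
    for (w in windows) {
      est <- youngs_modulus(curves[[i]], w)
      rows[[length(rows) + 1]] <-
        tibble::tibble(rate = rates[i], window_lo = w[1], window_hi = w[2],
                       E = est$E, residual = est$residual, n = est$n)
    }
  }
  do.call(rbind, rows)
}
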