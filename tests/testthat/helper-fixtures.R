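# Shared builders for tests. Samples follow the study conditions: gauge
# 8 mm / 1 mm-equivalent diameter strips for tissue-scale stiffness, the
# capillary elastomer geometry for the calibration fixtures.

tissue_scale_sample <- function(k, zeta = 0.5, l0 = 8e-3, d = 1e-3,
                                cell = buoyancy_cell()) {
  A <- pi * d^2 / 4
  virtual_sample(l0 = l0, A = A, k = k, c = 2 * zeta * sqrt(k * cell$m))
}

quiet_ccd <- function(...) ccd_config(noise_sd = 0, ...)

small_stiffening_sample <- function(E0 = 2e3, B = 4, l0 = 8e-3, d = 1e-3,
                                    c = 0) {
  virtual_sample(l0 = l0, A = pi * d^2 / 4, c = c,
                 nonlinear = list(E0 = E0, B = B))
}

design_poles <- c(-60, complex(real = -6.5, imaginary = c(1, -1)))

# worst-case distance between two unordered pole sets
pole_distance <- function(roots, target = design_poles) {
  max(vapply(target, function(t) min(Mod(roots - t)), numeric(1)))
}
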