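#' Reference elastomer moduli (device, mounting chamber with PBS)
#'
#' Young's moduli of the two polyvinyl-siloxane calibration elastomers as
#' measured on the instrument in the PBS-filled chamber, used as generating
#' parameters for the linear fixtures.
#'
#' @return Named vector of moduli in kPa.
#' @export
elastomer_moduli <- function() c(elite8 = 216.0, elite22 = 541.8)

#' Build a named virtual-sample fixture
#'
#' Fixtures emulate the study's specimens:
#'
#' * `elite8`, `elite22`: linear elastomers with E = 216.0 / 541.8 kPa,
#'   capillary-molded geometry (d = 0.58 mm, l0 = 3.0 mm; length-to-width
#'   ratio > 4:1). `elite8` lands at k = E A / l0 ~ 19 N/m, inside the
#'   controller design window k <= 20 N/m.
#' * `esophagus_wall`, `epithelium`, `stroma`, `muscle`, `epi_stroma`:
#'   strain-stiffening tissue strips (sigma = (E0/B)(e^{B eps} - 1)) with
#'   E0 and B set so the tangent modulus at the layer's physiological
#'   strain equals its measured modulus while the small-strain tangent
#'   stays below it (E0 = E_P / 3, B = ln(3) / eps_P). Geometry: strip of
#'   gauge length 8 mm and 1 mm equivalent diameter.
#'
#' Damping defaults to a 0.5 damping ratio against the moving-body mass and
#' the small-strain stiffness (no specimen viscosity is reported; this is a
#' documented artifact default). Pass `damping_ratio = 0` for a purely
#' elastic fixture.
#'
#' @param name Fixture name (see above).
#' @param damping_ratio Damping ratio used to derive `c` (default 0.5).
#' @param cell A [buoyancy_cell()] supplying the moving mass.
#' @return A list with `fixture` (metadata: name, kind, parameters,
#'   provenance note) and `sample` (a [virtual_sample()]).
#' @export
make_fixture <- function(name = c("elite8", "elite22", "esophagus_wall",
                                  "epithelium", "stroma", "muscle",
                                  "epi_stroma"),
                         damping_ratio = 0.5, cell = buoyancy_cell()) {
  name <- match.arg(name)
  if (name %in% c("elite8", "elite22")) {
    E <- elastomer_moduli()[[name]] * 1e3
    d <- 0.58e-3; l0 <- 3.0e-3
    A <- pi * d^2 / 4
    k <- E * A / l0
    c_damp <- 2 * damping_ratio * sqrt(k * cell$m)
    sample <- virtual_sample(l0 = l0, A = A, k = k, c = c_damp)
    fixture <- list(name = name, kind = "linear", E = E, d_mm = d * 1e3,
                    l0_mm = l0 * 1e3,
                    note = "capillary-molded PVS calibration elastomer")
  } else {
    tab <- esophagus_layers()
    key <- switch(name, esophagus_wall = "esophagus_experimental",
                  epi_stroma = "epithelium_stroma", name)
    row <- tab[tab$layer == key, ]
    eps_S <- tab$eps_S[tab$layer == "esophagus_experimental"]
    eps_P <- if (is.na(row$eps_P)) eps_S else row$eps_P
    E_P <- row$E_P_kPa * 1e3
    E0 <- E_P / 3
    B <- log(3) / eps_P          # tangent at eps_P equals E_P exactly
    d <- 1.0e-3; l0 <- 8.0e-3
    A <- pi * d^2 / 4
    k_tan0 <- E0 * A / l0
    c_damp <- 2 * damping_ratio * sqrt(k_tan0 * cell$m)
    sample <- virtual_sample(l0 = l0, A = A, c = c_damp,
                             nonlinear = list(E0 = E0, B = B))
    fixture <- list(name = name, kind = "stiffening", E0 = E0, B = B,
                    eps_P = eps_P, E_P = E_P, d_mm = d * 1e3,
                    l0_mm = l0 * 1e3,
                    note = "strain-stiffening strip; tangent at eps_P matches the measured layer modulus")
  }
  list(fixture = fixture, sample = sample)
}

#' List available fixture names
#' @return Character vector.
#' @export
fixture_names <- function() {
  c("elite8", "elite22", "esophagus_wall", "epithelium", "stroma",
    "muscle", "epi_stroma")
}
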