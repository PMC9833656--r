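#' Tissue layer of a composite wall
#'
#' Per-layer thickness, longitudinal residual strain and modulus at
#' physiological strain, optionally with a full stress law. The residual
#' strain is referenced to the cut-open, layer-separated length, so it may
#' be negative (a layer shorter in situ than when cut free).
#'
#' @param name Layer name.
#' @param h Thickness, um (Table-convention unit at this interface).
#' @param eps_R Longitudinal residual strain, dimensionless (> -1).
#' @param E_P Young's modulus at physiological strain, Pa (optional for
#'   bookkeeping-only layers).
#' @param law Optional stress law `function(eps) -> Pa`.
#' @return An object of class `tissue_layer`.
#' @export
tissue_layer <- function(name, h, eps_R = 0, E_P = NULL, law = NULL) {
  if (h <= 0) stop("thickness must be positive", call. = FALSE)
  if (eps_R <= -1) stop("residual strain must exceed -1", call. = FALSE)
  if (!is.null(E_P) && E_P <= 0)
    stop("modulus must be positive", call. = FALSE)
  structure(list(name = name, h = h, eps_R = eps_R, E_P = E_P, law = law),
            class = "tissue_layer")
}

#' Composite wall: ordered layers plus applied strain
#'
#' @param layers List of [tissue_layer()]s (>= 1).
#' @param eps_S Applied tensile strain, dimensionless.
#' @param total_thickness Optional intact-wall thickness, um; when given,
#'   the layer thicknesses must sum to it within 5%.
#' @return An object of class `composite_wall`.
#' @export
composite_wall <- function(layers, eps_S = 0, total_thickness = NULL) {
  if (length(layers) < 1) stop("need at least one layer", call. = FALSE)
  stopifnot(all(vapply(layers, inherits, logical(1), "tissue_layer")))
  h_sum <- sum(vapply(layers, function(l) l$h, numeric(1)))
  if (!is.null(total_thickness) &&
      abs(h_sum - total_thickness) > 0.05 * total_thickness)
    stop(sprintf(
      "layer thicknesses sum to %.4g um, inconsistent with the intact wall (%.4g um)",
      h_sum, total_thickness), call. = FALSE)
  structure(list(layers = layers, eps_S = eps_S), class = "composite_wall")
}

#' @export
print.composite_wall <- function(x, ...) {
  cat(sprintf("<composite_wall> %d layer(s), eps_S = %g\n",
              length(x$layers), x$eps_S))
  for (l in x$layers)
    cat(sprintf("  %-22s h = %7.2f um, eps_R = %+.3f%s\n", l$name, l$h,
                l$eps_R,
                if (!is.null(l$E_P)) sprintf(", E_P = %.3g kPa", l$E_P / 1e3)
                else ""))
  invisible(x)
}

#' Physiological strain of a layer
#'
#' The strain a layer experiences in situ during testing: residual plus
#' applied, `eps_P = eps_R + eps_S`.
#'
#' @param eps_R Residual strain (> -1).
#' @param eps_S Applied tensile strain (>= 0).
#' @return `eps_R + eps_S`.
#' @export
#' @examples
#' physiological_strain(0.02, 0.43)   # stroma: 0.45
#' physiological_strain(-0.21, 0.43)  # epithelium: 0.22
physiological_strain <- function(eps_R, eps_S) {
  if (any(eps_R <= -1)) stop("residual strain must exceed -1", call. = FALSE)
  if (any(eps_S < 0)) stop("applied strain must be non-negative",
                           call. = FALSE)
  eps_R + eps_S
}

#' Iso-strain composite modulus of a layered wall
#'
#' Rule of mixtures for layers sharing the applied strain (parallel
#' arrangement): the thickness-weighted mean of the layer moduli,
#' `E_wall = sum(h_i E_i) / sum(h_i)`. Bounded by the extreme layer moduli
#' and permutation-invariant.
#'
#' @param wall A [composite_wall()] whose layers all carry `E_P`.
#' @return Composite modulus, Pa.
#' @export
composite_modulus <- function(wall) {
  E <- vapply(wall$layers, function(l) {
    if (is.null(l$E_P)) stop(sprintf("layer '%s' has no modulus", l$name),
                             call. = FALSE)
    l$E_P
  }, numeric(1))
  h <- vapply(wall$layers, function(l) l$h, numeric(1))
  sum(h * E) / sum(h)
}

#' Full composite stress-strain prediction
#'
#' Each layer's stress law is evaluated at its residual-shifted strain and
#' combined by thickness weighting:
#' `sigma_wall(eps) = sum(h_i * sigma_i(eps + eps_R_i)) / sum(h_i)`.
#'
#' @param wall A [composite_wall()] whose layers all carry stress laws.
#' @param eps Applied strains at which to evaluate.
#' @return A [stress_strain_curve()] (geometry fields record the summed
#'   thickness in the area slot as NA-free placeholders are meaningless
#'   here; `A` and `l0` are set to 1).
#' @export
composite_curve <- function(wall, eps) {
  laws <- lapply(wall$layers, function(l) {
    if (is.null(l$law)) stop(sprintf("layer '%s' has no stress law", l$name),
                             call. = FALSE)
    l$law
  })
  h <- vapply(wall$layers, function(l) l$h, numeric(1))
  sigma <- rowSums(mapply(function(law, li) {
    s <- law(eps + wall$layers[[li]]$eps_R)
    if (any(!is.finite(s)))
      stop("stress law undefined at a shifted strain", call. = FALSE)
    s
  }, laws, seq_along(laws)) %*% diag(h, nrow = length(h))) / sum(h)
  stress_strain_curve(eps, sigma, A = 1, l0 = 1)
}

#' Esophageal layer reference table
#'
#' The packaged measurement table of the murine esophageal wall: per-layer
#' thickness, longitudinal residual strain, applied strain (intact wall),
#' physiological strain and modulus at physiological strain, with standard
#' deviations, plus the two- and three-layer model prediction rows.
#'
#' @return A tibble with columns `layer`, `h_um`, `h_sd_um`, `eps_R`,
#'   `eps_R_sd`, `eps_S`, `eps_S_sd`, `eps_P`, `eps_P_sd`, `E_P_kPa`,
#'   `E_P_sd_kPa`.
#' @export
esophagus_layers <- function() {
  path <- system.file("extdata", "esophagus_layers.tsv",
                      package = "tensiletwin", mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Composite-wall prediction from the packaged esophagus table
#'
#' Builds the two-layer (epithelium-and-stroma + muscle) or three-layer
#' (epithelium + stroma + muscle) wall from the packaged layer table and
#' returns the iso-strain modulus prediction.
#'
#' @param model `"two"` or `"three"`.
#' @param table Layer table (default [esophagus_layers()]).
#' @return List with `E_wall_kPa` (prediction), `reported_kPa` and
#'   `reported_sd_kPa` (the packaged model rows for comparison), and the
#'   `wall`.
#' @export
predict_wall_modulus <- function(model = c("two", "three"),
                                 table = esophagus_layers()) {
  model <- match.arg(model)
  names_needed <- if (model == "two") c("epithelium_stroma", "muscle")
                  else c("epithelium", "stroma", "muscle")
  rows <- table[match(names_needed, table$layer), ]
  if (any(is.na(rows$layer))) stop("layer table is missing rows",
                                   call. = FALSE)
  eps_S <- table$eps_S[table$layer == "esophagus_experimental"]
  layers <- lapply(seq_len(nrow(rows)), function(i)
    tissue_layer(rows$layer[i], h = rows$h_um[i], eps_R = rows$eps_R[i],
                 E_P = rows$E_P_kPa[i] * 1e3))
  wall <- composite_wall(layers, eps_S = eps_S,
                         total_thickness = table$h_um[
                           table$layer == "esophagus_experimental"])
  row_name <- paste0("esophagus_", model, "_layer_model")
  list(E_wall_kPa = composite_modulus(wall) / 1e3,
       reported_kPa = table$E_P_kPa[table$layer == row_name],
       reported_sd_kPa = table$E_P_sd_kPa[table$layer == row_name],
       wall = wall)
}
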