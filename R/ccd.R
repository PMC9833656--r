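#' Linear CCD sensor configuration
#'
#' Model of the line-scan shadow sensor: the bead casts a shadow on an array
#' of `n_pixels` photosites at `pitch` spacing, read at `frame_rate` and
#' digitized to `adc_bits`. The measurement channel adds Gaussian read noise
#' (in ADU), an integer frame delay (processing latency) and quantization.
#'
#' Default `noise_sd` is 12 ADU, a realistic read-noise level for an 8-bit
#' line CCD; with the default bright/dark levels it yields a static
#' localization precision of about 0.06 px (0.5 um), well inside the 0.2 px
#' (1.6 um) precision bound of the physical sensor.
#'
#' @param n_pixels Number of photosites (default 3648).
#' @param pitch Photosite spacing, m (default 8.0 um).
#' @param frame_rate Frames per second (default 200).
#' @param adc_bits ADC precision (default 8).
#' @param magnification Optical magnification from object to sensor plane
#'   (default 1.0, collimated LED-panel geometry).
#' @param noise_sd Additive Gaussian noise, ADU.
#' @param delay_frames Processing latency in whole frames. Default 0: the
#'   firmware localizes a frame and steps the controller within the same
#'   frame period, so no whole-frame delay accrues beyond the zero-order
#'   hold.
#' @param bright_level,dark_level Illuminated / shadowed signal levels, ADU.
#' @return An object of class `ccd_config`.
#' @export
ccd_config <- function(n_pixels = 3648, pitch = 8.0e-6, frame_rate = 200,
                       adc_bits = 8, magnification = 1.0, noise_sd = 12,
                       delay_frames = 0, bright_level = 220,
                       dark_level = 30) {
  adc_max <- 2^adc_bits - 1
  if (n_pixels <= 0 || pitch <= 0 || frame_rate <= 0 || magnification <= 0)
    stop("n_pixels, pitch, frame_rate, magnification must be positive",
         call. = FALSE)
  if (!(dark_level > 0 && dark_level < bright_level &&
        bright_level <= adc_max))
    stop("need 0 < dark_level < bright_level <= 2^adc_bits - 1",
         call. = FALSE)
  if (delay_frames < 0 || noise_sd < 0)
    stop("delay_frames and noise_sd must be non-negative", call. = FALSE)
  structure(list(n_pixels = as.integer(n_pixels), pitch = pitch,
                 frame_rate = frame_rate, adc_bits = as.integer(adc_bits),
                 magnification = magnification, noise_sd = noise_sd,
                 delay_frames = as.integer(delay_frames),
                 bright_level = bright_level, dark_level = dark_level),
            class = "ccd_config")
}

#' @export
print.ccd_config <- function(x, ...) {
  cat(sprintf(
    "<ccd_config> %d px @ %.3g um, %g Hz, %d-bit, M = %g, noise %g ADU, delay %d frame(s)\n",
    x$n_pixels, x$pitch * 1e6, x$frame_rate, x$adc_bits, x$magnification,
    x$noise_sd, x$delay_frames))
  invisible(x)
}

#' Span of the sensor in object-plane meters
#' @param config A [ccd_config()].
#' @return Length of the array divided by magnification, m.
#' @export
ccd_span <- function(config) config$n_pixels * config$pitch / config$magnification

#' Render a synthetic CCD frame of the bead shadow
#'
#' Pixels fully inside the shadow sit at `dark_level`, fully outside at
#' `bright_level`; edge pixels are linearly interpolated by their occluded
#' fraction (area sampling). Gaussian noise of sd `noise_sd` is added and
#' the result quantized to the ADC range. Uses the R RNG, so frames are
#' reproducible under `set.seed()`.
#'
#' @param bead_center Bead center in object-plane coordinates, m (the shadow
#'   spans `magnification * (bead_center +/- bead_diameter/2)` on the
#'   sensor).
#' @param bead_diameter Bead diameter, m.
#' @param config A [ccd_config()].
#' @param timestamp Frame time, s.
#' @return An object of class `ccd_frame`: list with integer `intensities`
#'   (ADU) and `timestamp`.
#' @export
render_shadow <- function(bead_center, bead_diameter,
                          config = ccd_config(), timestamp = 0) {
  # shadow extent in pixel units (pixel i spans [i-1, i])
  a <- config$magnification * (bead_center - bead_diameter / 2) / config$pitch
  b <- config$magnification * (bead_center + bead_diameter / 2) / config$pitch
  if (b <= 0 || a >= config$n_pixels)
    stop("shadow falls entirely off the sensor", call. = FALSE)
  i <- seq_len(config$n_pixels)
  frac <- pmax(0, pmin(i, b) - pmax(i - 1, a))   # occluded fraction per px
  v <- config$bright_level - frac * (config$bright_level - config$dark_level)
  if (config$noise_sd > 0)
    v <- v + stats::rnorm(config$n_pixels, sd = config$noise_sd)
  adc_max <- 2^config$adc_bits - 1
  v <- as.integer(round(pmax(0, pmin(adc_max, v))))
  structure(list(intensities = v, timestamp = timestamp),
            class = "ccd_frame")
}

#' Locate the bead shadow in a frame with sub-pixel precision
#'
#' Pixels are classified against the mid-threshold
#' `(bright + dark)/2`; the single dark run (wider than 2 px) is found, and
#' each edge is recovered by linearly inverting the occluded fraction of the
#' two pixels bracketing the transition (exact for area-sampled edges). The
#' estimate is the midpoint of the two edges, mapped to object-plane meters
#' via pitch and magnification. The calibrated plateau levels from the
#' configuration set the threshold and the contrast, as in the instrument
#' firmware.
#'
#' @param frame A [render_shadow()] frame.
#' @param config A [ccd_config()].
#' @return Estimated bead center in object-plane meters. Errors with class
#'   `tensiletwin_localization_failure` when no (or multiple) dark runs are
#'   present.
#' @export
locate_shadow <- function(frame, config = ccd_config()) {
  v <- as.numeric(frame$intensities)
  n <- length(v)
  thr <- (config$bright_level + config$dark_level) / 2
  dark <- v < thr
  r <- rle(dark)
  runs <- which(r$values & r$lengths > 2)
  if (length(runs) != 1) {
    stop(structure(class = c("tensiletwin_localization_failure",
                             "error", "condition"),
                   list(message = sprintf(
                     "localization failure: %d dark run(s) wider than 2 px",
                     length(runs)), call = NULL)))
  }
  ends <- cumsum(r$lengths)
  k1 <- ends[runs] - r$lengths[runs] + 1   # first dark pixel
  k2 <- ends[runs]                         # last dark pixel
  bright_hat <- config$bright_level
  contrast <- config$bright_level - config$dark_level
  occ <- function(idx) {
    if (idx < 1 || idx > n) return(0)
    max(0, min(1, (bright_hat - v[idx]) / contrast))
  }
  # left boundary a: occlusion accumulated in the two pixels at the
  # transition equals k1 - a; right boundary b symmetric.
  a_px <- k1 - occ(k1) - occ(k1 - 1)
  b_px <- (k2 - 1) + occ(k2) + occ(k2 + 1)
  (a_px + b_px) / 2 * config$pitch / config$magnification
}

#' Measurement channel: true positions to measured positions
#'
#' Renders and localizes each sample of a true-position stream (sampled at
#' the frame rate), emitting estimates `delay_frames` later. A localization
#' failure is propagated as a dropped-sample flag and the previous estimate
#' is held (as the controller firmware does).
#'
#' @param true_positions Object-plane bead centers, m (one per frame).
#' @param bead_diameter Bead diameter, m.
#' @param config A [ccd_config()].
#' @return A tibble with `measured` (m) and logical `dropped`.
#' @export
measurement_channel <- function(true_positions, bead_diameter,
                                config = ccd_config()) {
  n <- length(true_positions)
  est <- numeric(n)
  dropped <- logical(n)
  last <- NA_real_
  for (j in seq_len(n)) {
    e <- tryCatch(
      locate_shadow(render_shadow(true_positions[j], bead_diameter, config,
                                  timestamp = (j - 1) / config$frame_rate),
                    config),
      tensiletwin_localization_failure = function(cnd) NA_real_,
      error = function(cnd) NA_real_)  # off-sensor render is also a drop
    if (is.na(e)) {
      dropped[j] <- TRUE
      e <- if (is.na(last)) true_positions[j] else last
    }
    est[j] <- e
    last <- e
  }
  d <- config$delay_frames
  measured <- if (d > 0 && n > 0) {
    c(rep(est[1], min(d, n)), est[seq_len(max(0, n - d))])
  } else est
  tibble::tibble(measured = measured,
                 dropped = c(rep(FALSE, min(d, n)),
                             dropped[seq_len(max(0, n - d))]))
}

#' Write a frame as delimited text (pixel index, ADU)
#'
#' @param frame A [render_shadow()] frame.
#' @param path Output file.
#' @export
write_frame <- function(frame, path) {
  utils::write.table(
    data.frame(pixel = seq_along(frame$intensities),
               adu = frame$intensities),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
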