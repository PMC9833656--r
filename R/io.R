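# Configuration, trace files and small I/O plumbing. Configs are YAML with
# unit-tagged scalars ("8 mm", or {value: 8, unit: mm}); traces are
# self-describing delimited text (comment header + TSV body).

.unit_table <- list(
  length = c(m = 1, mm = 1e-3, um = 1e-6),
  area = c("m^2" = 1, "mm^2" = 1e-6),
  stiffness = c("N/m" = 1),
  damping = c("N s/m" = 1, "N.s/m" = 1),
  current = c(A = 1, mA = 1e-3),
  force_const = c("N/(A^2 m^3)" = 1, "N A^-2 m^-3" = 1),
  pressure = c(Pa = 1, kPa = 1e3, MPa = 1e6),
  frequency = c(Hz = 1),
  time = c(s = 1, ms = 1e-3),
  mass = c(kg = 1, g = 1e-3, mg = 1e-6),
  density = c("kg/m^3" = 1),
  rate = c("1/s" = 1),
  dimensionless = stats::setNames(c(1, 1), c("1", "")),
  adu = c(ADU = 1),
  gain_p = c("A/m" = 1),
  gain_i = c("A/(m s)" = 1),
  gain_d = c("A s/m" = 1)
)

.config_schema <- list(
  magnet = list(F0 = "force_const", x0 = "length", I_max = "current"),
  bead = list(d = "length", density = "density"),
  cell = list(c_d = "damping", cell_mass = "mass", m = "mass"),
  sample = list(l0 = "length", A = "area", d = "length", k = "stiffness",
                c = "damping", E0 = "pressure", B = "dimensionless"),
  ccd = list(n_pixels = "count", pitch = "length", frame_rate = "frequency",
             adc_bits = "count", magnification = "dimensionless",
             noise_sd = "adu", delay_frames = "count",
             bright_level = "adu", dark_level = "adu"),
  controller = list(p1 = "rate", p2_real = "rate", p2_imag = "rate",
                    Ki_max = "gain_i", I_max = "current",
                    I_clamp = "current", k_hat_max = "stiffness",
                    q_min = "length", c_hat = "damping",
                    I_init = "current", I_op_min = "current",
                    deriv_tau = "time", k_hat_tau = "time",
                    bootstrap_Kp = "gain_p",
                    bootstrap_Ki = "gain_i", bootstrap_Kd = "gain_d"),
  protocol = list(kind = "string", strain_rate = "rate",
                  target_strain = "dimensionless", n_cycles = "count"),
  x_start = "length",
  seed = "count"
)

.parse_quantity <- function(raw, kind, where) {
  if (kind == "string") {
    if (!is.character(raw) || length(raw) != 1)
      stop(sprintf("config error at %s: expected a string", where),
           call. = FALSE)
    return(raw)
  }
  if (kind == "count") {
    if (!is.numeric(raw) || length(raw) != 1 || raw != round(raw))
      stop(sprintf("config error at %s: expected a bare integer", where),
           call. = FALSE)
    return(as.integer(raw))
  }
  if (is.list(raw) && all(c("value", "unit") %in% names(raw))) {
    value <- raw$value; unit <- as.character(raw$unit)
  } else if (is.character(raw) && length(raw) == 1) {
    parts <- regmatches(raw, regexec("^\\s*([-+0-9.eE]+)\\s*(.*)$", raw))[[1]]
    if (length(parts) != 3)
      stop(sprintf("config error at %s: cannot parse quantity '%s'",
                   where, raw), call. = FALSE)
    value <- as.numeric(parts[2]); unit <- trimws(parts[3])
  } else {
    stop(sprintf(
      "config error at %s: physical quantities need a unit tag ('8 mm' or {value, unit})",
      where), call. = FALSE)
  }
  table <- .unit_table[[kind]]
  hit <- which(names(table) == unit)
  if (length(hit) != 1)
    stop(sprintf("config error at %s: unit '%s' is not a %s unit (allowed: %s)",
                 where, unit, kind,
                 paste(sprintf("'%s'", names(table)), collapse = ", ")),
         call. = FALSE)
  value * unname(table[hit])
}

.parse_block <- function(raw, schema, where) {
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0)
    stop(sprintf("config error: unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  out <- list()
  for (key in names(raw))
    out[[key]] <- .parse_quantity(raw[[key]], schema[[key]],
                                  paste(where, key, sep = "."))
  out
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with unit-tagged physical quantities, checks
#' units and ranges, and materializes the package's parameter objects.
#' Unknown keys are rejected; missing blocks fall back to package defaults.
#'
#' @param path YAML file.
#' @return An object of class `run_config`: list with `magnet`, `bead`,
#'   `cell`, `sample`, `ccd`, `controller`, `protocol`, `x_start`, `seed`
#'   and the normalized `raw` values.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(.config_schema))
  if (length(unknown) > 0)
    stop("config error: unknown top-level key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  g <- function(block) {
    if (is.null(raw[[block]])) list()
    else .parse_block(raw[[block]], .config_schema[[block]], block)
  }
  mg <- g("magnet"); bd <- g("bead"); cl <- g("cell"); sm <- g("sample")
  cc <- g("ccd"); ct <- g("controller"); pr <- g("protocol")

  magnet <- do.call(electromagnet_params, mg)
  bead <- do.call(bead_spec, bd)
  cell_args <- cl; cell_args$bead <- bead
  cell <- do.call(buoyancy_cell, cell_args)

  if (is.null(sm$l0)) stop("config error: sample.l0 is required",
                           call. = FALSE)
  if (is.null(sm$A)) {
    if (is.null(sm$d))
      stop("config error: sample needs A or d", call. = FALSE)
    sm$A <- pi * sm$d^2 / 4
  }
  sample <- if (!is.null(sm$E0)) {
    virtual_sample(sm$l0, sm$A, c = sm$c %||% 0,
                   nonlinear = list(E0 = sm$E0, B = sm$B %||% 0))
  } else {
    virtual_sample(sm$l0, sm$A, k = sm$k %||% 0, c = sm$c %||% 0)
  }

  ccd <- do.call(ccd_config, cc)
  poles <- pole_placement_spec(p1 = ct$p1 %||% -60,
                               p2_real = ct$p2_real %||% -6.5,
                               p2_imag = ct$p2_imag %||% 1)
  boot <- pid_gains(Kp = ct$bootstrap_Kp %||% 50,
                    Ki = ct$bootstrap_Ki %||% 500,
                    Kd = ct$bootstrap_Kd %||% 0)
  ctrl_args <- ct[setdiff(names(ct),
                          c("p1", "p2_real", "p2_imag",
                            "bootstrap_Kp", "bootstrap_Ki",
                            "bootstrap_Kd"))]
  ctrl_args$poles <- poles; ctrl_args$bootstrap <- boot
  controller <- do.call(controller_config, ctrl_args)

  protocol <- if (length(pr) > 0) {
    make_reference(kind = pr$kind %||% "ramp",
                   strain_rate = pr$strain_rate %||% 2e-3,
                   target_strain = pr$target_strain %||% 0.1,
                   n_cycles = pr$n_cycles %||% 1, l0 = sample$l0)
  } else NULL

  x_start <- if (!is.null(raw$x_start))
    .parse_quantity(raw$x_start, "length", "x_start") else 8e-3
  seed <- if (!is.null(raw$seed))
    .parse_quantity(raw$seed, "count", "seed") else 1L

  structure(list(magnet = magnet, bead = bead, cell = cell,
                 sample = sample, ccd = ccd, controller = controller,
                 protocol = protocol, x_start = x_start, seed = seed,
                 raw = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes the raw unit-tagged representation back to YAML, so
#' `load_config(save_config(cfg, f))` round-trips.
#'
#' @param config A [load_config()] result (or a raw list in the same
#'   schema).
#' @param path Output file.
#' @export
save_config <- function(config, path) {
  raw <- if (inherits(config, "run_config")) config$raw else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Stable content hash of a configuration
#'
#' Polynomial rolling hash over the canonical deparsed form; used to stamp
#' traces and logs so any output can be matched to the exact configuration
#' that produced it.
#'
#' @param config Any R object.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.trace_columns <- c("t_s", "q_ref_m", "q_true_m", "q_meas_m", "I_A",
                    "F_E_N", "F_spring_N", "F_drag_N", "Kp", "Ki", "Kd",
                    "k_hat", "flags")

#' Write a simulation trace as self-describing delimited text
#'
#' A comment header (`# key: value`) records seed, geometry, magnet/bead
#' parameters and a configuration hash; the body is tab-separated at full
#' double precision, so read-back is lossless.
#'
#' @param trace A [run_closed_loop()] trace.
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  s <- trace$sample
  nl <- !is.null(s$nonlinear)
  meta <- c(seed = trace$seed, x_start = trace$x_start,
            l0 = s$l0, A = s$A, k = s$k, c = s$c,
            nonlinear = as.integer(nl),
            E0 = if (nl) s$nonlinear$E0 else 0,
            B = if (nl) s$nonlinear$B else 0,
            F0 = trace$magnet$F0, x0 = trace$magnet$x0,
            I_max = trace$magnet$I_max, bead_d = trace$bead$d,
            frame_rate = trace$ccd$frame_rate)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %.17g", names(meta), meta), con)
  writeLines(sprintf("# config_hash: %s",
                     config_hash(trace[c("sample", "cell", "magnet", "bead",
                                         "ccd", "controller", "reference",
                                         "x_start", "seed", "n_sub")])),
             con)
  writeLines(paste(.trace_columns, collapse = "\t"), con)
  body <- trace$data[, .trace_columns]
  writeLines(do.call(paste, c(lapply(body, function(col) {
    if (is.integer(col)) as.character(col) else sprintf("%.17g", col)
  }), sep = "\t")), con)
  invisible(path)
}

#' Read a simulation trace file
#'
#' @param path A [write_trace()] file.
#' @return A `simulation_trace` carrying the data and the header metadata
#'   needed by [trace_to_curve()] (sample geometry, magnet, bead, x_start).
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  meta <- stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) stop("schema error: trace has no data rows",
                             call. = FALSE)
  cols <- strsplit(body[1], "\t")[[1]]
  if (!identical(cols, .trace_columns))
    stop("schema error: unexpected trace columns", call. = FALSE)
  cells <- strsplit(body[-1], "\t")
  if (any(lengths(cells) != length(.trace_columns)))
    stop("schema error: truncated or ragged trace body", call. = FALSE)
  mat <- do.call(rbind, lapply(cells, as.numeric))
  data <- tibble::as_tibble(stats::setNames(as.data.frame(mat),
                                            .trace_columns))
  data$flags <- as.integer(data$flags)
  num <- function(key) as.numeric(meta[[key]])
  nl <- num("nonlinear") == 1
  sample <- virtual_sample(num("l0"), num("A"), k = num("k"), c = num("c"),
                           nonlinear = if (nl)
                             list(E0 = num("E0"), B = num("B")) else NULL)
  structure(list(data = data, sample = sample,
                 magnet = electromagnet_params(num("F0"), num("x0"),
                                               num("I_max")),
                 bead = bead_spec(d = num("bead_d")),
                 ccd = ccd_config(frame_rate = num("frame_rate")),
                 x_start = num("x_start"), seed = as.integer(num("seed")),
                 reference = NULL,
                 config_hash = meta[["config_hash"]]),
            class = "simulation_trace")
}

#' Read a bare two-column force record
#'
#' Delimited text with columns elongation (m) and force (N); a header row
#' is detected and skipped.
#'
#' @param path Input file.
#' @return Tibble with `elongation_m`, `force_N`.
#' @export
read_elongation_force <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^[-+0-9.eE \t,]+$", first)
  df <- utils::read.table(path, header = has_header,
                          sep = if (grepl(",", first)) "," else "",
                          comment.char = "#")
  if (ncol(df) < 2)
    stop("expected two columns: elongation_m, force_N", call. = FALSE)
  tibble::tibble(elongation_m = as.numeric(df[[1]]),
                 force_N = as.numeric(df[[2]]))
}
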