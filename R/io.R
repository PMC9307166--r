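# Formats and configuration: the ASCII sensor-stream dialect, calibration
# files with checksums, and YAML setup configuration.

#' Parse a sensor data stream
#'
#' Reads the magnetometer wire dialect: one sample per line, three
#' space-separated ASCII signed integers in `[-32768, 32767]`, each line
#' terminated by CR LF. Parsing is tolerant of trailing whitespace and a
#' missing final line terminator, but strict on arity and range; errors
#' name the offending line.
#'
#' @param x Path to a stream file, or a character scalar holding the
#'   stream, or a character vector of lines.
#' @return Integer matrix (n x 3) with attribute `lines` (source line
#'   numbers).
#' @export
parse_sensor_stream <- function(x) {
  lines <- if (length(x) == 1L && (file.exists(x) || grepl("[\r\n]", x))) {
    if (file.exists(x)) {
      readLines(x, warn = FALSE)
    } else {
      strsplit(gsub("\r\n", "\n", x), "\n", fixed = TRUE)[[1]]
    }
  } else {
    x
  }
  lines <- sub("[ \t\r]+$", "", lines)
  keep <- nzchar(lines)
  out <- matrix(0L, sum(keep), 3)
  lineno <- which(keep)
  for (i in seq_along(lineno)) {
    ln <- lineno[i]
    parts <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(parts) != 3L) {
      stop(sprintf("line %d: expected 3 values, got %d", ln, length(parts)),
           call. = FALSE)
    }
    v <- suppressWarnings(as.integer(parts))
    if (any(is.na(v)) || any(parts != as.character(v))) {
      stop(sprintf("line %d: not a signed integer triplet: '%s'",
                   ln, lines[ln]), call. = FALSE)
    }
    if (any(v < -32768L) || any(v > 32767L)) {
      stop(sprintf("line %d: value out of the 16-bit range [-32768, 32767]",
                   ln), call. = FALSE)
    }
    out[i, ] <- v
  }
  attr(out, "lines") <- lineno
  out
}

#' Write a sensor data stream
#'
#' Writes integer triplets in the wire dialect of [parse_sensor_stream()]:
#' space-separated values, CR LF line terminators, bit-exact round trip.
#'
#' @param triplets Integer matrix (n x 3) in `[-32768, 32767]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_stream <- function(triplets, path) {
  triplets <- as.matrix(triplets)
  stopifnot(ncol(triplets) == 3L)
  if (any(triplets < -32768) || any(triplets > 32767) ||
      any(triplets != round(triplets))) {
    stop("triplets must be integers in [-32768, 32767]", call. = FALSE)
  }
  txt <- paste(sprintf("%d %d %d\r\n",
                       triplets[, 1], triplets[, 2], triplets[, 3]),
               collapse = "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  invisible(path)
}

# simple additive checksum of the payload lines (documented, not
# cryptographic): sum of UTF-8 byte values modulo 2^31 - 1
line_checksum <- function(lines) {
  s <- 0
  for (ln in lines) s <- (s + sum(utf8ToInt(ln)) + 10) %% 2147483647
  s
}

fmt_nums <- function(x) paste(sprintf("%.17g", x), collapse = " ")

#' Serialize a calibration to a text file
#'
#' Writes a sensor ([fit_ellipsoid()]) or setup ([fit_calibration()])
#' calibration as self-describing structured text: type, units, matrices
#' at full precision (round trip is lossless), creation metadata, and an
#' additive checksum over the payload.
#'
#' @param calib An `ellipsoid_calibration` or `coil_calibration` object.
#' @param path Output file path.
#' @param comment Optional free-text comment line.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path, comment = NULL) {
  if (inherits(calib, "ellipsoid_calibration")) {
    lines <- c(
      "magstimkit-calibration",
      "type: sensor",
      "version: 1",
      "units: W_inv dimensionless; V_bias LSB; g_mag nT/LSB; fit_rms uT",
      paste0("W_inv: ", fmt_nums(t(calib$W_inv))),
      paste0("V_bias: ", fmt_nums(calib$V_bias)),
      paste0("g_mag: ", fmt_nums(calib$g_mag)),
      paste0("fit_rms: ", fmt_nums(calib$fit_rms)),
      paste0("reference_magnitude: ", fmt_nums(calib$reference_magnitude))
    )
  } else if (inherits(calib, "coil_calibration")) {
    lines <- c(
      "magstimkit-calibration",
      "type: setup",
      "version: 1",
      "units: D uT/V; B_const uT; residual_std uT",
      paste0("D: ", fmt_nums(t(calib$D))),
      paste0("B_const: ", fmt_nums(calib$B_const)),
      paste0("residual_std: ", fmt_nums(calib$residual_std)),
      paste0("condition_number: ", fmt_nums(calib$condition_number)),
      paste0("n: ", calib$n)
    )
  } else {
    stop("unsupported calibration object", call. = FALSE)
  }
  if (!is.null(comment)) lines <- c(lines, paste0("comment: ", comment))
  lines <- c(lines, paste0("created: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  lines <- c(lines, paste0("checksum: ", line_checksum(lines)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialized calibration
#'
#' Reads files written by [write_calibration()], verifying the checksum
#' and, optionally, the calibration type.
#'
#' @param path File path.
#' @param expected_type `"sensor"`, `"setup"`, or `NULL` to accept either.
#' @return The reconstructed calibration object.
#' @export
read_calibration <- function(path, expected_type = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1] != "magstimkit-calibration") {
    stop("not a magstimkit calibration file", call. = FALSE)
  }
  ck_line <- grep("^checksum: ", lines)
  if (length(ck_line) != 1L) stop("missing checksum", call. = FALSE)
  stated <- as.numeric(sub("^checksum: ", "", lines[ck_line]))
  actual <- line_checksum(lines[seq_len(ck_line - 1L)])
  if (stated != actual) {
    stop("checksum mismatch: file corrupted or edited", call. = FALSE)
  }
  field <- function(name) {
    ln <- grep(paste0("^", name, ": "), lines, value = TRUE)
    if (length(ln) == 0L) stop(sprintf("missing field '%s'", name),
                               call. = FALSE)
    sub(paste0("^", name, ": "), "", ln[1])
  }
  nums <- function(name) as.numeric(strsplit(field(name), " ")[[1]])
  type <- field("type")
  if (!is.null(expected_type) && type != expected_type) {
    stop(sprintf("calibration type mismatch: file is '%s', expected '%s'",
                 type, expected_type), call. = FALSE)
  }
  if (type == "sensor") {
    structure(list(W_inv = matrix(nums("W_inv"), 3, 3, byrow = TRUE),
                   V_bias = nums("V_bias"), g_mag = nums("g_mag"),
                   fit_rms = nums("fit_rms"),
                   reference_magnitude = nums("reference_magnitude")),
              class = "ellipsoid_calibration")
  } else if (type == "setup") {
    structure(list(D = matrix(nums("D"), 3, 3, byrow = TRUE),
                   B_const = nums("B_const"),
                   residual_std = nums("residual_std"),
                   condition_number = nums("condition_number"),
                   n = as.integer(field("n")), joint_intercept = NA),
              class = "coil_calibration")
  } else {
    stop(sprintf("unknown calibration type '%s'", type), call. = FALSE)
  }
}

#' Read a setup configuration file
#'
#' Loads a YAML configuration describing the coil geometry (per-axis
#' shape, size, separation, turns, axis, center, polarity), and optional
#' sensor, driver and ambient-field blocks. Unknown top-level keys are
#' rejected. An example file reproducing the reference three-axis system
#' ships with the package:
#' `system.file("extdata", "example_setup.yaml", package = "magstimkit")`.
#'
#' @param path YAML file path.
#' @return List with `pairs` (list of [coil_geometry()]), and any of
#'   `sensor` ([sensor_model()]), `driver` ([driver_model()]), `ambient`
#'   (microtesla 3-vector), `seed`.
#' @export
read_setup_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("geometry", "sensor", "driver", "ambient", "seed", "mea")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0L) {
    stop("unknown configuration keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  if (!is.null(cfg$geometry)) {
    out$pairs <- lapply(cfg$geometry, function(g) {
      coil_geometry(shape = g$shape %||% "square",
                    size = g$size,
                    separation = g$separation %||%
                      optimal_square_separation(g$size),
                    turns = g$turns %||% 1,
                    axis = unlist(g$axis) %||% c(0, 0, 1),
                    center = unlist(g$center) %||% c(0, 0, 0),
                    polarity = g$polarity %||% "serial")
    })
  }
  if (!is.null(cfg$sensor)) {
    s <- cfg$sensor
    out$sensor <- sensor_model(
      V_bias = unlist(s$V_bias) %||% c(0, 0, 0),
      W = if (is.null(s$W)) diag(3) else matrix(unlist(s$W), 3, 3, byrow = TRUE),
      g_mag = s$g_mag %||% 7.85,
      noise_std = s$noise_std %||% 0.54,
      full_scale = s$full_scale %||% 200,
      output_rate = s$output_rate %||% 200)
  }
  if (!is.null(cfg$driver)) {
    d <- cfg$driver
    out$driver <- driver_model(
      R_shunt = d$R_shunt %||% 1,
      control_divider = d$control_divider %||% 1,
      supply = d$supply %||% 15,
      dropout = d$dropout %||% 4,
      current_limit = d$current_limit %||% 3,
      coil_R = d$coil_R %||% 10.1,
      coil_L = d$coil_L %||% 1.05e-3,
      zeta = d$zeta %||% 0.517,
      omega_n = d$omega_n)
  }
  if (!is.null(cfg$ambient)) out$ambient <- as_vec3(unlist(cfg$ambient))
  if (!is.null(cfg$seed)) out$seed <- as.integer(cfg$seed)
  out$mea <- cfg$mea
  out
}
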