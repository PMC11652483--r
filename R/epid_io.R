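#' Raw EPID frame
#'
#' A single 16-bit portal image as exported by the acquisition system. Pixel
#' intensities are *inversely* proportional to dose (the panel calibration
#' maps zero dose to 65535); use [invert_raw()] to obtain a dose-proportional
#' image.
#'
#' @param pixels Integer-valued matrix, values in `[0, 65535]`.
#' @param frame_index 0-based frame index within the acquisition.
#' @param timestamp Seconds from acquisition start.
#' @return An object of class `raw_frame`.
#' @export
raw_frame <- function(pixels, frame_index, timestamp) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) != ncol(pixels)) stop("frame must be square")
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 65535) {
    stop("pixel values must lie in [0, 65535]")
  }
  if (any(pixels != round(pixels))) stop("pixel values must be integers")
  stopifnot(frame_index >= 0, is.finite(timestamp))
  structure(list(pixels = pixels, frame_index = as.integer(frame_index),
                 timestamp = as.numeric(timestamp)),
            class = "raw_frame")
}

#' EPID acquisition log
#'
#' Per-frame sidecar written by the acquisition system: frame timestamps and
#' the pixel scaling factor (PSF) used to convert processed intensities to
#' MU-equivalent values. Note that in this context PSF is a *scalar per-frame
#' normalization constant*, not a point-spread function.
#'
#' @param frame_times Strictly increasing vector of seconds.
#' @param psf_values Positive per-frame pixel scaling factors.
#' @return An object of class `acquisition_log`.
#' @export
acquisition_log <- function(frame_times, psf_values) {
  if (length(frame_times) != length(psf_values)) {
    stop("frame_times and psf_values must have equal length")
  }
  if (length(frame_times) > 1 && any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing")
  }
  if (any(psf_values <= 0)) stop("psf_values must be positive")
  structure(list(n_frames = length(frame_times),
                 frame_times = as.numeric(frame_times),
                 psf_values = as.numeric(psf_values)),
            class = "acquisition_log")
}

## ---- 16-bit PGM frame files -------------------------------------------------
## Frames are stored one per file as 16-bit grayscale PGM ("P5" binary,
## big-endian sample order per the netpbm spec; "P2" ASCII also accepted).
## PGM is used instead of a compressed raster format so the frame store is
## self-describing plain data with no image-library dependency.

#' Write a 16-bit PGM image
#'
#' @param pixels Integer matrix in `[0, 65535]`.
#' @param path Output file.
#' @param ascii Write the ASCII ("P2") dialect instead of binary "P5".
#' @export
write_pgm <- function(pixels, path, ascii = FALSE) {
  pixels <- as.matrix(pixels)
  stopifnot(all(pixels >= 0), all(pixels <= 65535))
  v <- as.integer(round(t(pixels)))  # row-major raster order
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(pixels), nrow(pixels)), "65535"), con)
    writeLines(paste(v, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n65535\n", ncol(pixels), nrow(pixels)),
              con, eos = NULL)
    # big-endian 16-bit samples; bytes written manually (writeBin size=2 is signed)
    writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con)
  }
  invisible(path)
}

#' Read a 16-bit PGM image
#'
#' Accepts binary "P5" and ASCII "P2" files with maxval 65535. An 8-bit file
#' (maxval 255) is rescaled by 257 to the 16-bit range and flagged with a
#' warning, mirroring acquisition systems that export lossy 8-bit rasters.
#'
#' @param path PGM file.
#' @return Integer matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) stop("unexpected end of PGM header: ", path)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok) > 0) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (!maxval %in% c(255L, 65535L)) stop("unsupported PGM maxval: ", maxval)
  n <- w * h
  if (magic == "P5") {
    size <- if (maxval > 255L) 2L else 1L
    v <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                 endian = "big")
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(v) != n) stop("truncated PGM raster: ", path)
  if (maxval == 255L) {
    warning("8-bit PGM rescaled x257 to 16-bit (degraded source): ", path)
    v <- v * 257L
  }
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

## ---- frame sequence store ---------------------------------------------------
## Layout: <dir>/frame_NNNN.pgm (NNNN = 0-based index) plus one
## <dir>/acquisition.log sidecar:
##   # EPIDACQ/1.0
##   # n_frames: <N>
##   <index> <time_s> <psf>
## one line per frame, whitespace separated.

#' Write a frame sequence with its acquisition log
#'
#' @param frames List of [raw_frame()] objects.
#' @param log An [acquisition_log()] with one entry per frame.
#' @param directory_path Output directory (created if missing).
#' @param ascii Store frames as ASCII PGM.
#' @export
write_frame_sequence <- function(frames, log, directory_path, ascii = FALSE) {
  if (length(frames) != log$n_frames) {
    stop("frame count does not match acquisition log")
  }
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  for (f in frames) {
    write_pgm(f$pixels,
              file.path(directory_path, sprintf("frame_%04d.pgm", f$frame_index)),
              ascii = ascii)
  }
  lines <- c("# EPIDACQ/1.0",
             sprintf("# n_frames: %d", log$n_frames),
             sprintf("%d %.6f %.8g", seq_len(log$n_frames) - 1L,
                     log$frame_times, log$psf_values))
  writeLines(lines, file.path(directory_path, "acquisition.log"))
  invisible(directory_path)
}

#' Read a frame sequence
#'
#' Reads `frame_NNNN.pgm` files and the `acquisition.log` sidecar from a
#' directory, ordered by frame index and timestamped from the log.
#'
#' @param directory_path Directory holding the frames and log.
#' @param config Optional [detector_geometry()]; frames must match its
#'   resolution when given.
#' @return List with `frames` (list of [raw_frame()]) and `log`
#'   ([acquisition_log()]); class `raw_frame_sequence`.
#' @export
read_frame_sequence <- function(directory_path, config = NULL) {
  log_path <- file.path(directory_path, "acquisition.log")
  if (!file.exists(log_path)) stop("missing acquisition log: ", log_path)
  lines <- readLines(log_path)
  data <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  fields <- do.call(rbind, lapply(strsplit(trimws(data), "[[:space:]]+"),
                                  as.numeric))
  if (is.null(fields) || ncol(fields) != 3) {
    stop("malformed acquisition log: ", log_path)
  }
  ord <- order(fields[, 1])
  fields <- fields[ord, , drop = FALSE]
  log <- acquisition_log(fields[, 2], fields[, 3])
  files <- sort(list.files(directory_path, pattern = "^frame_[0-9]+\\.pgm$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no frames found in ", directory_path)
  if (length(files) != log$n_frames) {
    stop(sprintf("frame count mismatch: %d frame files but log says n_frames=%d",
                 length(files), log$n_frames))
  }
  frames <- vector("list", length(files))
  for (k in seq_along(files)) {
    px <- read_pgm(files[k])
    if (!is.null(config) && nrow(px) != config$resolution) {
      stop(sprintf("frame %s is %dx%d, expected %d", basename(files[k]),
                   nrow(px), ncol(px), config$resolution))
    }
    idx <- as.integer(sub("^frame_0*([0-9]+)\\.pgm$", "\\1", basename(files[k])))
    frames[[k]] <- raw_frame(px, idx, log$frame_times[k])
  }
  frames <- frames[order(vapply(frames, `[[`, 0L, "frame_index"))]
  structure(list(frames = frames, log = log), class = "raw_frame_sequence")
}

## ---- VMAT plans -------------------------------------------------------------

#' VMAT plan control point
#'
#' Machine-state snapshot: gantry and collimator angle, cumulative MU, and
#' the two MLC banks. `bank_A` holds the left (more negative cross-plane)
#' leaf edges, `bank_B` the right edges, both in mm at the isocenter plane,
#' signed about the beam axis.
#'
#' @param index 0-based control point index.
#' @param gantry_angle Degrees in `[0, 360)`.
#' @param collimator_angle Degrees in `[-180, 180)`.
#' @param cumulative_mu MU delivered up to this control point.
#' @param bank_A,bank_B Numeric vectors of equal length (one value per pair).
#' @return An object of class `plan_control_point`.
#' @export
plan_control_point <- function(index, gantry_angle, collimator_angle,
                               cumulative_mu, bank_A, bank_B) {
  stopifnot(length(bank_A) == length(bank_B), cumulative_mu >= 0,
            gantry_angle >= 0, gantry_angle < 360,
            collimator_angle >= -180, collimator_angle < 180)
  if (any(bank_B < bank_A - 1e-9)) stop("bank_B must be >= bank_A")
  structure(list(index = as.integer(index),
                 gantry_angle = as.numeric(gantry_angle),
                 collimator_angle = as.numeric(collimator_angle),
                 cumulative_mu = as.numeric(cumulative_mu),
                 bank_A = as.numeric(bank_A), bank_B = as.numeric(bank_B)),
            class = "plan_control_point")
}

#' VMAT plan
#'
#' An ordered arc of control points for one beam.
#'
#' @param plan_id Free-text identifier.
#' @param beam_energy Beam label, e.g. `"6"` or `"6 FFF"`.
#' @param control_points List of [plan_control_point()], >= 2, with
#'   non-decreasing cumulative MU.
#' @param leaf_widths Leaf widths in mm (one per pair).
#' @return An object of class `vmat_plan`.
#' @export
vmat_plan <- function(plan_id, beam_energy, control_points, leaf_widths) {
  if (length(control_points) < 2) {
    stop("a VMAT arc needs at least 2 control points (static beam?)")
  }
  n_pairs <- length(control_points[[1]]$bank_A)
  stopifnot(length(leaf_widths) == n_pairs)
  mu <- vapply(control_points, `[[`, 0, "cumulative_mu")
  if (any(diff(mu) < 0)) stop("cumulative MU must be non-decreasing")
  for (cp in control_points) {
    if (length(cp$bank_A) != n_pairs) stop("inconsistent bank length")
  }
  structure(list(plan_id = plan_id, beam_energy = beam_energy,
                 total_mu = mu[length(mu)], control_points = control_points,
                 n_leaf_pairs = n_pairs, leaf_widths = as.numeric(leaf_widths)),
            class = "vmat_plan")
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat(sprintf("<vmat_plan> %s | %s MV | %d control points | %d leaf pairs | %.4g MU\n",
              x$plan_id, x$beam_energy, length(x$control_points),
              x$n_leaf_pairs, x$total_mu))
  invisible(x)
}

#' Write a VMAT plan (RTPLAN-JSON/1.0)
#'
#' Serializes the arc as a JSON document. This open dialect stands in for the
#' clinical DICOM RT-Plan transfer format: it carries the same control-point
#' payload (angles, cumulative MU weights, per-leaf bank positions in mm at
#' isocenter) in a plain-text container.
#'
#' @param plan A [vmat_plan()].
#' @param path Output file.
#' @export
write_rtplan <- function(plan, path) {
  doc <- list(
    format = "RTPLAN-JSON/1.0",
    plan_id = plan$plan_id,
    beam_energy = plan$beam_energy,
    n_leaf_pairs = plan$n_leaf_pairs,
    leaf_widths_mm = plan$leaf_widths,
    control_points = lapply(plan$control_points, function(cp) {
      list(index = cp$index, gantry_angle = cp$gantry_angle,
           collimator_angle = cp$collimator_angle,
           cumulative_mu = cp$cumulative_mu,
           bank_A_mm = cp$bank_A, bank_B_mm = cp$bank_B)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a VMAT plan (RTPLAN-JSON/1.0)
#'
#' @param path Plan file written by [write_rtplan()].
#' @return A [vmat_plan()].
#' @export
read_rtplan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "RTPLAN-JSON/1.0")) {
    stop("not an RTPLAN-JSON/1.0 document: ", path)
  }
  cps <- lapply(doc$control_points, function(cp) {
    plan_control_point(cp$index, cp$gantry_angle, cp$collimator_angle,
                       cp$cumulative_mu, cp$bank_A_mm, cp$bank_B_mm)
  })
  vmat_plan(doc$plan_id, doc$beam_energy, cps, doc$leaf_widths_mm)
}

## ---- Table 3 fixture --------------------------------------------------------

#' Read the 18-plan gamma passing rate / complexity table
#'
#' Loads the per-plan table of gamma passing rates (proposed EPID-log QA and
#' machine-log QA, 0-100 scale) together with twelve plan complexity and
#' transition metrics. With `path = NULL` the packaged transcription is used.
#'
#' @param path CSV file; `NULL` for the packaged fixture.
#' @return A `data.frame` with 18 rows.
#' @export
read_table3 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "plan_gpr_complexity.csv",
                        package = "epidlog", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expected <- c("site", "beam", "mu", "gpr_prop", "gpr_mach", "sas", "mcsv",
                "lt", "ltmcs", "aav", "lsv", "mlc_mn", "mlc_sn", "mlc_mx",
                "mlc_sx", "mu_mean", "mu_std")
  if (!identical(names(tab), expected)) {
    stop("unexpected columns: ", paste(names(tab), collapse = ", "))
  }
  if (nrow(tab) != 18) stop("expected 18 plan rows, got ", nrow(tab))
  num <- expected[-(1:2)]
  for (cn in num) {
    if (any(is.na(tab[[cn]]))) {
      stop(sprintf("missing value in column '%s' (row %d)", cn,
                   which(is.na(tab[[cn]]))[1]))
    }
  }
  tab
}
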