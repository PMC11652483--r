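#' EPID-derived machine log
#'
#' The end product of the pipeline: one record per EPID frame carrying the
#' machine state recovered from the image (gantry/collimator angle,
#' cumulative MU, both MLC banks in mm at isocenter). Serialized as the
#' open, versioned EPIDLOG/1.0 text dialect: a `# key: value` header block
#' followed by one tab-separated line per record with positions to 0.01 mm,
#' MU to 0.0001 and angles to 0.01 degrees. Axis convention: IEC 61217,
#' cross-plane positions signed about the beam axis.
#'
#' @param records data.frame with columns `frame_index`, `time_s`,
#'   `gantry_deg`, `collimator_deg`, `cumulative_mu`.
#' @param bank_A,bank_B Numeric matrices, one row per record, one column per
#'   leaf pair.
#' @param header Named list; recognised keys include `plan_id`,
#'   `beam_energy`, `total_mu`, `frame_period_s`, `calibration_ids`. Unknown
#'   keys are preserved on round-trip.
#' @return An object of class `epid_log`.
#' @export
epid_log <- function(records, bank_A, bank_B, header = list()) {
  bank_A <- as.matrix(bank_A); bank_B <- as.matrix(bank_B)
  n <- nrow(records)
  if (nrow(bank_A) != n || nrow(bank_B) != n || ncol(bank_A) != ncol(bank_B)) {
    stop("bank matrices must have one row per record and equal width")
  }
  if (any(diff(records$cumulative_mu) < -1e-9)) {
    bad <- which(diff(records$cumulative_mu) < -1e-9)[1] + 1L
    stop("cumulative MU decreases at record ", bad)
  }
  header$n_leaf_pairs <- ncol(bank_A)
  structure(list(header = header, records = records,
                 bank_A = bank_A, bank_B = bank_B),
            class = "epid_log")
}

#' @export
print.epid_log <- function(x, ...) {
  cat(sprintf("<epid_log> %d records x %d leaf pairs | plan %s | %.4g MU\n",
              nrow(x$records), x$header$n_leaf_pairs,
              x$header$plan_id %||% "?",
              utils::tail(x$records$cumulative_mu, 1)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_log_line <- function(rec, a, b) {
  paste(c(sprintf("%d", rec$frame_index),
          sprintf("%.3f", rec$time_s),
          sprintf("%.2f", rec$gantry_deg),
          sprintf("%.2f", rec$collimator_deg),
          sprintf("%.4f", rec$cumulative_mu),
          sprintf("%.2f", a), sprintf("%.2f", b)),
        collapse = "\t")
}

#' Write an EPIDLOG/1.0 file
#'
#' Re-serializing a parsed file reproduces it byte for byte (all fields are
#' stored at the declared precision).
#'
#' @param log An [epid_log()].
#' @param path Output file.
#' @export
write_epid_log <- function(log, path) {
  stopifnot(inherits(log, "epid_log"))
  h <- log$header
  keys <- names(h)
  lines <- c("# EPIDLOG/1.0",
             vapply(keys, function(k) {
               sprintf("# %s: %s", k, paste(format(h[[k]], trim = TRUE),
                                            collapse = ","))
             }, ""))
  n <- nrow(log$records)
  body <- vapply(seq_len(n), function(i) {
    fmt_log_line(log$records[i, ], log$bank_A[i, ], log$bank_B[i, ])
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read an EPIDLOG/1.0 file
#'
#' @param path Log file.
#' @return An [epid_log()]; unknown header keys are preserved.
#' @export
read_epid_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != "# EPIDLOG/1.0") {
    stop("not an EPIDLOG/1.0 file: ", path)
  }
  hdr_lines <- grep("^#", lines, value = TRUE)[-1]
  header <- list()
  for (hl in hdr_lines) {
    m <- regmatches(hl, regexec("^# ([^:]+): (.*)$", hl))[[1]]
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      header[[m[2]]] <- if (!anyNA(num)) num else val
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) stop("log has no records")
  n_pairs <- as.integer(header$n_leaf_pairs %||% NA)
  parsed <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop("malformed record at line ", i + length(hdr_lines) + 1L)
    v
  })
  width <- lengths(parsed)
  if (is.na(n_pairs)) n_pairs <- (width[1] - 5L) %/% 2L
  bad <- which(width != 5L + 2L * n_pairs)
  if (length(bad)) {
    stop("truncated or malformed record at data line ", bad[1])
  }
  mat <- do.call(rbind, parsed)
  records <- data.frame(frame_index = as.integer(mat[, 1]), time_s = mat[, 2],
                        gantry_deg = mat[, 3], collimator_deg = mat[, 4],
                        cumulative_mu = mat[, 5])
  epid_log(records,
           bank_A = mat[, 5L + seq_len(n_pairs), drop = FALSE],
           bank_B = mat[, 5L + n_pairs + seq_len(n_pairs), drop = FALSE],
           header = header)
}
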