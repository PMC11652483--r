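#' Pipeline configuration
#'
#' All tunables of the frame-to-log pipeline with their defaults. The
#' configuration serializes to JSON (round-trip stable) and every run can
#' write its resolved configuration next to its outputs.
#'
#' @param detector List: `resolution` (px), `pixel_mm`.
#' @param deconv List: `sigma` (px), `tol`, `max_iter`.
#' @param threshold List: `value` (absolute intensity; `NULL` = 50% of each
#'   frame's maximum), `grid_step`, `tolerance` (calibration sweep).
#' @param mu List: `stat` (`"mean"`/`"sum"`), `angle_map` (`"mu"`/`"time"`).
#' @param complexity List: `sas_gap_mm`, `lt_norm_mm`.
#' @param gamma List: `dd`, `dta`, `cut`.
#' @param seed Integer seed for stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(detector = list(resolution = 512L, pixel_mm = 0.5),
                            deconv = list(sigma = 2, tol = 1e-4, max_iter = 50L),
                            threshold = list(value = NULL, grid_step = 100,
                                             tolerance = 0.02),
                            mu = list(stat = "mean", angle_map = "mu"),
                            complexity = list(sas_gap_mm = 10, lt_norm_mm = 500),
                            gamma = list(dd = 3, dta = 3, cut = 0.10),
                            seed = 1L) {
  stopifnot(detector$resolution >= 16, detector$pixel_mm > 0,
            deconv$sigma > 0, deconv$tol > 0, deconv$max_iter >= 1,
            mu$stat %in% c("mean", "sum"), mu$angle_map %in% c("mu", "time"))
  structure(list(detector = detector, deconv = deconv, threshold = threshold,
                 mu = mu, complexity = complexity, gamma = gamma,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for the writer).
#' @export
read_pipeline_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, doc[intersect(names(doc), names(formals(pipeline_config)))])
}

#' Process an in-memory acquisition into an EPID log
#'
#' Core of the pipeline: per frame invert the raw image, deconvolve,
#' binarize, extract per-leaf edges (with in-plane band re-indexing when an
#' offset model is supplied), convert intensities to MU-equivalents via the
#' PSF, then assign cumulative MU and gantry angles across frames and apply
#' the cross-plane offset correction at each frame's pose.
#'
#' @param frames List of [raw_frame()].
#' @param log An [acquisition_log()].
#' @param plan A [vmat_plan()].
#' @param config A [pipeline_config()].
#' @param offsets Optional [measure_center_offsets()] model.
#' @return An [epid_log()].
#' @export
process_acquisition <- function(frames, log, plan, config = pipeline_config(),
                                offsets = NULL) {
  geometry <- detector_geometry(config$detector$resolution,
                                config$detector$pixel_mm)
  kernel <- gaussian_kernel(config$deconv$sigma)
  n <- length(frames)
  if (n != log$n_frames) stop("stage epid_io: frame/log count mismatch")
  mu_equiv <- numeric(n)
  aps <- vector("list", n)
  for (k in seq_len(n)) {
    processed <- invert_raw(frames[[k]])
    dec <- iterative_deconvolve(processed, kernel, tol = config$deconv$tol,
                                max_iter = config$deconv$max_iter)
    thr <- config$threshold$value
    if (is.null(thr)) thr <- max(dec$image$values) / 2
    mask <- binarize(dec$image, thr)
    aps[[k]] <- extract_leaf_edges(mask, geometry, plan$leaf_widths,
                                   frame_index = k - 1L)
    mu_equiv[k] <- frame_mu(processed, log$psf_values[k], mask,
                            stat = config$mu$stat)
  }
  records <- assign_frame_records(mu_equiv, plan, log,
                                  angle_map = config$mu$angle_map)
  n_pairs <- plan$n_leaf_pairs
  bank_A <- bank_B <- matrix(0, n, n_pairs)
  for (k in seq_len(n)) {
    ap <- aps[[k]]
    if (!is.null(offsets)) {
      # in-plane correction re-reads the frame with shifted leaf bands
      row_shift <- pose_in_offset(offsets, records$gantry_deg[k],
                                  records$collimator_deg[k])
      if (abs(row_shift) >= 0.5) {
        processed <- invert_raw(frames[[k]])
        dec <- iterative_deconvolve(processed, kernel,
                                    tol = config$deconv$tol,
                                    max_iter = config$deconv$max_iter)
        thr <- config$threshold$value
        if (is.null(thr)) thr <- max(dec$image$values) / 2
        ap <- extract_leaf_edges(binarize(dec$image, thr), geometry,
                                 plan$leaf_widths, frame_index = k - 1L,
                                 band_row_shift = round(row_shift))
      }
      ap <- apply_offset_correction(ap, records$gantry_deg[k],
                                    records$collimator_deg[k], offsets,
                                    geometry)
    }
    bank_A[k, ] <- ap$pairs$left_mm
    bank_B[k, ] <- ap$pairs$right_mm
  }
  header <- list(plan_id = plan$plan_id, beam_energy = plan$beam_energy,
                 total_mu = plan$total_mu,
                 frame_period_s = if (n > 1) round(stats::median(diff(log$frame_times)), 6) else NA,
                 calibration_ids = if (is.null(offsets)) "none" else "offsets")
  epid_log(records, bank_A, bank_B, header)
}

#' Run the full pipeline from files on disk
#'
#' Reads a frame directory and a plan file, executes
#' [process_acquisition()], writes the EPIDLOG/1.0 file and a run manifest
#' (resolved configuration) next to it.
#'
#' @param frames_dir Directory with `frame_NNNN.pgm` files and
#'   `acquisition.log`.
#' @param plan_path An RTPLAN-JSON/1.0 file.
#' @param out_path Output log file.
#' @param config A [pipeline_config()].
#' @param calibration_path Optional EPIDCAL/1.0 JSON with threshold and
#'   offset calibration.
#' @param use_offsets Require and apply the offset model from the
#'   calibration file.
#' @return The [epid_log()] (invisibly); side effects: `out_path` and
#'   `<out_path>.config.json`.
#' @export
run_pipeline <- function(frames_dir, plan_path, out_path,
                         config = pipeline_config(),
                         calibration_path = NULL, use_offsets = FALSE) {
  seqc <- read_frame_sequence(frames_dir)
  plan <- read_rtplan(plan_path)
  offsets <- NULL
  if (!is.null(calibration_path)) {
    cal <- read_calibration(calibration_path)
    if (!is.null(cal$threshold)) config$threshold$value <- cal$threshold
    offsets <- cal$offsets
  }
  if (use_offsets && is.null(offsets)) {
    stop("offset correction requested but no offset model found; run the ",
         "offset calibration and pass its EPIDCAL/1.0 file")
  }
  log <- process_acquisition(seqc$frames, seqc$log, plan, config, offsets)
  write_epid_log(log, out_path)
  write_pipeline_config(config, paste0(out_path, ".config.json"))
  invisible(log)
}

#' Command-line entry point
#'
#' Dispatches the `epidlog` subcommands (`simulate`, `convert`,
#' `complexity`, `correlate`, `table3-stats`, `validate`). Installed as
#' `exec/epidlog`; call from R as `epidlog_main(c("table3-stats"))`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
epidlog_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: epidlog <command> [args]",
    "  simulate --preset {boxes,arc,offsets} --out DIR [--seed N] [--frames N]",
    "  convert --frames DIR --plan FILE --out FILE [--sigma S] [--calibration FILE]",
    "  complexity --plan FILE [--out FILE]",
    "  correlate [--table FILE] [--out FILE]",
    "  table3-stats",
    "  validate --frames DIR --log FILE", sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0) default else args[i[1] + 1]
  }
  switch(cmd,
    "table3-stats" = {
      cat(jsonlite::toJSON(reproduce_table3_stats(), auto_unbox = TRUE,
                           digits = NA), "\n")
    },
    "correlate" = {
      tab <- read_table3(opt("table"))
      res <- correlate_table3(tab)
      out <- opt("out")
      if (is.null(out)) print(res) else utils::write.csv(res, out, row.names = FALSE)
    },
    "complexity" = {
      plan <- read_rtplan(opt("plan"))
      rep_ <- plan_complexity(plan)
      json <- jsonlite::toJSON(unclass(rep_), auto_unbox = TRUE, digits = NA)
      out <- opt("out")
      if (is.null(out)) cat(json, "\n") else writeLines(json, out)
    },
    "simulate" = {
      preset <- opt("preset", "arc")
      outdir <- opt("out", ".")
      seed <- as.integer(opt("seed", "1"))
      if (preset == "arc") {
        plan <- synthetic_arc_plan()
        acq <- gen_vmat_acquisition(plan, n_frames = as.integer(opt("frames", "60")),
                                    seed = seed)
        write_frame_sequence(acq$frames, acq$log, outdir)
        write_rtplan(plan, file.path(outdir, "plan.json"))
      } else if (preset == "boxes") {
        bx <- gen_box_series()
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        for (k in seq_along(bx$raw)) {
          write_pgm(bx$raw[[k]]$pixels,
                    file.path(outdir, sprintf("box_%02dcm.pgm", bx$sizes_cm[k])))
        }
      } else stop("unknown preset: ", preset)
      cat("wrote", preset, "preset to", outdir, "\n")
    },
    "convert" = {
      cfg <- pipeline_config()
      sig <- opt("sigma"); if (!is.null(sig)) cfg$deconv$sigma <- as.numeric(sig)
      run_pipeline(opt("frames"), opt("plan"), opt("out", "run.epidlog"),
                   config = cfg, calibration_path = opt("calibration"))
      cat("wrote", opt("out", "run.epidlog"), "\n")
    },
    stop("unknown command: ", cmd, "\n", usage)
  )
  invisible(0L)
}
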