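#' Binarize a deconvolved fluence image
#'
#' @param image A [fluence_image()] with `stage = "deconvolved"` (synthetic
#'   `"ideal"` images are also accepted for ground-truth work).
#' @param threshold Intensity cut; pixels `>= threshold` are in-aperture.
#' @return An object of class `binary_aperture` (`mask`, `threshold_used`).
#' @export
binarize <- function(image, threshold) {
  stopifnot(inherits(image, "fluence_image"))
  if (image$stage == "processed") {
    stop("binarize expects a deconvolved (or ideal) image")
  }
  if (threshold <= 0) stop("threshold must be > 0")
  mask <- image$values >= threshold
  if (!any(mask)) warning("empty aperture: no pixel reaches the threshold")
  structure(list(mask = mask, threshold_used = threshold),
            class = "binary_aperture")
}

# Cross-plane open width of the central leaf band, in pixels: number of
# above-threshold pixels per row, averaged over a band of 2*band rows about
# the image center.
central_band_width <- function(mask, band = 5L) {
  n <- nrow(mask)
  rows <- (n %/% 2L - band + 1L):(n %/% 2L + band)
  mean(rowSums(mask[rows, , drop = FALSE]))
}

#' Calibrate the binarization threshold from box-field linearity
#'
#' Given deconvolved images of square box fluences at 5, 10, 15 and 20 cm
#' nominal side, sweeps candidate thresholds over 40-60% of the maximum
#' pixel value and, for each candidate, measures the cross-plane pixel width
#' of the central leaf band of each binarized box. A candidate is valid when
#' the 10/5, 15/5 and 20/5 width ratios hit 2, 3 and 4 within `ratio_tol`.
#' The chosen threshold is the midpoint of the maximal contiguous valid
#' interval.
#'
#' @param box_images List of four deconvolved [fluence_image()]s, ordered
#'   small to large (5, 10, 15, 20 cm).
#' @param grid_step Candidate spacing in absolute intensity units.
#' @param ratio_tol Allowed deviation of each ratio from its integer target.
#' @return An object of class `threshold_calibration` with
#'   `candidate_thresholds`, `linearity_table` (3 x K matrix of ratios),
#'   `valid_range` and `chosen`.
#' @export
calibrate_threshold <- function(box_images, grid_step = 100, ratio_tol = 0.02) {
  if (length(box_images) != 4) stop("need exactly four box images")
  widths0 <- vapply(box_images, function(im) {
    central_band_width(im$values >= max(im$values) / 2)
  }, 0)
  if (anyDuplicated(round(widths0)) > 0) {
    stop("degenerate input: two box images have the same field width")
  }
  vmax <- max(vapply(box_images, function(im) max(im$values), 0))
  cands <- seq(ceiling(0.4 * vmax / grid_step) * grid_step, 0.6 * vmax,
               by = grid_step)
  ratios <- sapply(cands, function(thr) {
    w <- vapply(box_images, function(im) central_band_width(im$values >= thr), 0)
    if (w[1] <= 0) return(c(NA_real_, NA_real_, NA_real_))
    w[2:4] / w[1]
  })
  rownames(ratios) <- c("r10_5", "r15_5", "r20_5")
  ok <- !is.na(ratios[1, ]) &
    abs(ratios[1, ] - 2) <= ratio_tol &
    abs(ratios[2, ] - 3) <= ratio_tol &
    abs(ratios[3, ] - 4) <= ratio_tol
  if (!any(ok)) {
    dev <- colSums(abs(ratios - c(2, 3, 4)))
    best <- which.min(replace(dev, is.na(dev), Inf))
    stop(sprintf(paste0("no threshold satisfies the 2/3/4 linearity; best ",
                        "candidate %g gives ratios %.3f/%.3f/%.3f"),
                 cands[best], ratios[1, best], ratios[2, best],
                 ratios[3, best]))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  iv <- which(runs$values)
  pick <- iv[which.max(runs$lengths[iv])]
  lo <- cands[starts[pick]]; hi <- cands[ends[pick]]
  structure(list(candidate_thresholds = cands, linearity_table = ratios,
                 valid_range = c(lo, hi), chosen = (lo + hi) / 2),
            class = "threshold_calibration")
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("<threshold_calibration> chosen %g (valid %g-%g over %d candidates)\n",
              x$chosen, x$valid_range[1], x$valid_range[2],
              length(x$candidate_thresholds)))
  invisible(x)
}

# longest TRUE run of a logical vector; returns c(start, end) 1-based
# inclusive, or NULL if none; n_runs attribute counts disjoint runs
longest_run <- function(x) {
  r <- rle(x)
  idx <- which(r$values)
  if (length(idx) == 0) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pick <- idx[which.max(r$lengths[idx])]
  structure(c(starts[pick], ends[pick]), n_runs = length(idx))
}

#' Extract per-leaf-pair edges from a binary aperture
#'
#' Each leaf pair is read from its projected row band: a column counts as
#' open when at least half of the band rows are above threshold, and the
#' aperture of the pair is the longest contiguous open run (extra disjoint
#' runs trigger an island-artifact warning). Edges use half-open column
#' spans converted to signed mm at the isocenter plane; pairs without an
#' open run are reported closed at the park position.
#'
#' @param mask A [binarize()] result.
#' @param geometry A [detector_geometry()].
#' @param leaf_widths Leaf widths in mm (one per pair).
#' @param frame_index Frame index recorded in the result.
#' @param park_mm Position reported for both edges of a closed pair.
#' @param band_row_shift Integer row offset applied to the leaf bands before
#'   extraction (in-plane detector offset correction).
#' @return An object of class `leaf_aperture`: `frame_index` and `pairs`, a
#'   data.frame with `leaf_index`, `left_mm`, `right_mm`, `open`.
#' @export
extract_leaf_edges <- function(mask, geometry, leaf_widths, frame_index = 0L,
                               park_mm = 0, band_row_shift = 0L) {
  stopifnot(inherits(mask, "binary_aperture"))
  bands <- leaf_row_bands(leaf_widths, geometry)
  bands <- bands + as.integer(round(band_row_shift))
  if (min(bands) < 1L || max(bands) > nrow(mask$mask)) {
    stop("leaf bands fall outside the detector after row shift")
  }
  n_pairs <- nrow(bands)
  left <- right <- rep(as.numeric(park_mm), n_pairs)
  open <- logical(n_pairs)
  islands <- FALSE
  for (i in seq_len(n_pairs)) {
    band <- mask$mask[bands[i, "first"]:bands[i, "last"], , drop = FALSE]
    colopen <- colMeans(band) >= 0.5
    run <- longest_run(colopen)
    if (is.null(run)) next
    if (attr(run, "n_runs") > 1L) islands <- TRUE
    # half-open span: left boundary = run[1]-1 (0-based), right = run[2]
    left[i] <- boundary_to_mm(run[1] - 1L, geometry)
    right[i] <- boundary_to_mm(run[2], geometry)
    open[i] <- TRUE
  }
  if (islands) warning("disjoint open runs in a leaf band; kept the longest")
  structure(list(frame_index = as.integer(frame_index),
                 pairs = data.frame(leaf_index = seq_len(n_pairs),
                                    left_mm = left, right_mm = right,
                                    open = open)),
            class = "leaf_aperture")
}

## ---- detector offset model --------------------------------------------------

# edge/center landmarks of one (nominally 10x10 cm) box image, integer-pixel
# precision: left/right first/last open columns of the central row band,
# top/bottom first/last open rows of the central column band
box_landmarks <- function(values) {
  mask <- values >= max(values) / 2
  n <- nrow(mask); m <- ncol(mask)
  rows <- (n %/% 2L - 4L):(n %/% 2L + 5L)
  cols_open <- colMeans(mask[rows, , drop = FALSE]) >= 0.5
  cols <- (m %/% 2L - 4L):(m %/% 2L + 5L)
  rows_open <- rowMeans(mask[, cols, drop = FALSE]) >= 0.5
  cr <- longest_run(cols_open); rr <- longest_run(rows_open)
  if (is.null(cr) || is.null(rr)) stop("no aperture found in offset image")
  c(left = cr[1] - 1, right = cr[2], top = rr[1] - 1, bottom = rr[2])
}

#' Measure detector center offsets over gantry and collimator poses
#'
#' Builds an offset model from 10 x 10 cm box images acquired over two
#' calibration grids: a gantry-sag grid (gantry 0-350 degrees in 10-degree
#' steps, collimator 0) and a collimator-shift grid (gantry 0-330 in
#' 30-degree steps crossed with collimator -90..90 in 30-degree steps).
#' Offsets are landmark positions minus those at the reference pose (gantry
#' 0, collimator 0), in pixels; the collimator tables store the *additional*
#' shift beyond the sag measured at the same gantry angle.
#'
#' @param sag_images Named list of images (matrices or [fluence_image()]s);
#'   names `"g<angle>"` for each gantry angle of `gantry_grid`.
#' @param coll_images Named list; names `"g<gantry>_c<collimator>"` over the
#'   collimator grids.
#' @param gantry_grid,coll_gantry_grid,coll_grid Calibration grids (degrees).
#' @return An object of class `offset_model`.
#' @export
measure_center_offsets <- function(sag_images, coll_images = NULL,
                                   gantry_grid = seq(0, 350, by = 10),
                                   coll_gantry_grid = seq(0, 330, by = 30),
                                   coll_grid = seq(-90, 90, by = 30)) {
  getv <- function(x) if (inherits(x, "fluence_image")) x$values else x
  want <- sprintf("g%g", gantry_grid)
  miss <- setdiff(want, names(sag_images))
  if (length(miss)) stop("missing sag grid pose(s): ", paste(miss, collapse = ", "))
  lm <- sapply(want, function(nm) box_landmarks(getv(sag_images[[nm]])))
  ref <- lm[, "g0"]
  sag <- sweep(lm, 1, ref)
  model <- list(gantry_grid = gantry_grid,
                sag_cross_left = unname(sag["left", ]),
                sag_cross_right = unname(sag["right", ]),
                sag_in_upper = unname(sag["top", ]),
                sag_in_lower = unname(sag["bottom", ]),
                coll_gantry_grid = coll_gantry_grid,
                coll_grid = coll_grid,
                coll_shift_cross = matrix(0, length(coll_gantry_grid),
                                          length(coll_grid)),
                coll_shift_in = matrix(0, length(coll_gantry_grid),
                                       length(coll_grid)))
  if (!is.null(coll_images)) {
    for (gi in seq_along(coll_gantry_grid)) {
      g <- coll_gantry_grid[gi]
      sag_cross_g <- stats::approx(c(gantry_grid, 360),
                                   c((sag["left", ] + sag["right", ]) / 2,
                                     (sag["left", 1] + sag["right", 1]) / 2),
                                   xout = g %% 360)$y
      sag_in_g <- stats::approx(c(gantry_grid, 360),
                                c((sag["top", ] + sag["bottom", ]) / 2,
                                  (sag["top", 1] + sag["bottom", 1]) / 2),
                                xout = g %% 360)$y
      for (ci in seq_along(coll_grid)) {
        nm <- sprintf("g%g_c%g", g, coll_grid[ci])
        if (is.null(coll_images[[nm]])) {
          stop(sprintf("missing collimator grid pose gantry=%g collimator=%g",
                       g, coll_grid[ci]))
        }
        l <- box_landmarks(getv(coll_images[[nm]])) - ref
        model$coll_shift_cross[gi, ci] <- (l["left"] + l["right"]) / 2 - sag_cross_g
        model$coll_shift_in[gi, ci] <- (l["top"] + l["bottom"]) / 2 - sag_in_g
      }
    }
  }
  structure(model, class = "offset_model")
}

#' A zero (identity) offset model
#' @return An `offset_model` with all offsets 0.
#' @export
zero_offset_model <- function() {
  measure <- list(gantry_grid = seq(0, 350, by = 10),
                  coll_gantry_grid = seq(0, 330, by = 30),
                  coll_grid = seq(-90, 90, by = 30))
  structure(c(measure[1],
              list(sag_cross_left = numeric(36), sag_cross_right = numeric(36),
                   sag_in_upper = numeric(36), sag_in_lower = numeric(36)),
              measure[2:3],
              list(coll_shift_cross = matrix(0, 12, 7),
                   coll_shift_in = matrix(0, 12, 7))),
            class = "offset_model")
}

# periodic linear interpolation of a gantry-indexed table
interp_gantry <- function(grid, values, gantry) {
  g <- gantry %% 360
  stats::approx(c(grid, 360), c(values, values[1]), xout = g)$y
}

# bilinear interpolation over (gantry x collimator); periodic in gantry
interp_coll <- function(model, table, gantry, collimator) {
  if (collimator < min(model$coll_grid) || collimator > max(model$coll_grid)) {
    stop("collimator angle outside the calibrated grid")
  }
  g <- gantry %% 360
  gg <- c(model$coll_gantry_grid, 360)
  tt <- rbind(table, table[1, ])
  gi <- max(which(gg <= g)); gi <- min(gi, length(gg) - 1L)
  wg <- (g - gg[gi]) / (gg[gi + 1] - gg[gi])
  row <- (1 - wg) * tt[gi, ] + wg * tt[gi + 1, ]
  stats::approx(model$coll_grid, row, xout = collimator)$y
}

# total cross-plane offsets (left edge, right edge) in pixels at a pose
pose_cross_offsets <- function(model, gantry, collimator) {
  coll <- interp_coll(model, model$coll_shift_cross, gantry, collimator)
  c(left = interp_gantry(model$gantry_grid, model$sag_cross_left, gantry) + coll,
    right = interp_gantry(model$gantry_grid, model$sag_cross_right, gantry) + coll)
}

# total in-plane offset (rows, mean of upper/lower) in pixels at a pose
pose_in_offset <- function(model, gantry, collimator) {
  sag <- (interp_gantry(model$gantry_grid, model$sag_in_upper, gantry) +
          interp_gantry(model$gantry_grid, model$sag_in_lower, gantry)) / 2
  sag + interp_coll(model, model$coll_shift_in, gantry, collimator)
}

#' Correct extracted leaf edges for detector offsets at a pose
#'
#' Subtracts the interpolated cross-plane detector offset (gantry sag plus
#' collimator shift, in pixels) from the extracted edges: sag is
#' interpolated linearly and periodically in gantry angle, per bank; the
#' collimator term bilinearly over its (gantry x collimator) grid. In-plane
#' offsets act on the leaf-band indexing and are applied *before* extraction
#' (see `band_row_shift` of [extract_leaf_edges()]), not here.
#'
#' @param ap A [extract_leaf_edges()] result.
#' @param gantry,collimator Pose angles in degrees.
#' @param model An [measure_center_offsets()] result.
#' @param geometry A [detector_geometry()] (pixel pitch for the mm shift).
#' @return The corrected `leaf_aperture`.
#' @export
apply_offset_correction <- function(ap, gantry, collimator, model, geometry) {
  stopifnot(inherits(ap, "leaf_aperture"), inherits(model, "offset_model"))
  off <- pose_cross_offsets(model, gantry, collimator)
  open <- ap$pairs$open
  ap$pairs$left_mm[open] <- ap$pairs$left_mm[open] - off["left"] * geometry$pixel_mm
  ap$pairs$right_mm[open] <- ap$pairs$right_mm[open] - off["right"] * geometry$pixel_mm
  ap
}

#' Save / load calibration artifacts as JSON
#'
#' Stores a threshold calibration and an offset model so a pipeline run can
#' reuse machine calibration.
#'
#' @param threshold A [calibrate_threshold()] result (or `NULL`).
#' @param offsets An [measure_center_offsets()] result (or `NULL`).
#' @param path JSON file.
#' @export
write_calibration <- function(threshold = NULL, offsets = NULL, path) {
  doc <- list(format = "EPIDCAL/1.0")
  if (!is.null(threshold)) {
    doc$threshold <- list(chosen = threshold$chosen,
                          valid_range = threshold$valid_range)
  }
  if (!is.null(offsets)) doc$offsets <- unclass(offsets)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @return `read_calibration()` returns a list with elements `threshold`
#'   (numeric or `NULL`) and `offsets` (`offset_model` or `NULL`).
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "EPIDCAL/1.0")) {
    stop("not an EPIDCAL/1.0 document: ", path)
  }
  out <- list(threshold = NULL, offsets = NULL)
  if (!is.null(doc$threshold)) out$threshold <- doc$threshold$chosen
  if (!is.null(doc$offsets)) {
    m <- doc$offsets
    m$coll_shift_cross <- as.matrix(m$coll_shift_cross)
    m$coll_shift_in <- as.matrix(m$coll_shift_in)
    out$offsets <- structure(m, class = "offset_model")
  }
  out
}
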