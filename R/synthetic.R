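## Synthetic acquisition generator.
##
## Emulates the frame-by-frame portal-image export of a rotating linac with
## known ground truth: ideal binary aperture fluences are rasterized on the
## detector grid, scaled by the per-frame dose, convolved with a Gaussian
## scatter kernel, optionally degraded with multiplicative noise, and
## inverted to the 16-bit raw convention. The per-frame pixel scaling factor
## is set so that the MU conversion recovers the true frame dose exactly on
## noiseless data. All generators are pure functions of their arguments and
## the seed.

# Rasterize one aperture (per-pair left/right edges in mm) as an ideal
# binary fluence scaled to `plateau`. Edge boundaries are rounded to the
# pixel grid (the panel cannot resolve sub-pixel edges).
rasterize_aperture <- function(left_mm, right_mm, leaf_widths, geometry,
                               plateau = 40000) {
  n <- geometry$resolution
  img <- matrix(0, n, n)
  bands <- leaf_row_bands(leaf_widths, geometry)
  for (i in seq_along(left_mm)) {
    if (right_mm[i] <= left_mm[i]) next
    a <- as.integer(round(mm_to_boundary(left_mm[i], geometry)))
    b <- as.integer(round(mm_to_boundary(right_mm[i], geometry)))
    a <- max(a, 0L); b <- min(b, n)
    if (b <= a) next
    img[bands[i, "first"]:bands[i, "last"], (a + 1L):b] <- plateau
  }
  img
}

# square box fluence of side `size_mm` centered on the beam axis, shifted by
# (shift_col, shift_row) pixels
rasterize_box <- function(size_mm, geometry, plateau = 40000,
                          shift_col = 0, shift_row = 0) {
  n <- geometry$resolution
  half_px <- size_mm / 2 / geometry$pixel_mm
  c0 <- as.integer(round(n / 2 - half_px + shift_col))
  c1 <- as.integer(round(n / 2 + half_px + shift_col))
  r0 <- as.integer(round(n / 2 - half_px + shift_row))
  r1 <- as.integer(round(n / 2 + half_px + shift_row))
  if (c0 < 0 || r0 < 0 || c1 > n || r1 > n) stop("box exceeds detector")
  img <- matrix(0, n, n)
  img[(r0 + 1L):r1, (c0 + 1L):c1] <- plateau
  img
}

# ideal fluence -> 16-bit raw frame (blur, optional noise, invert)
fluence_to_raw <- function(ideal, kernel, noise_sd = 0) {
  v <- if (kernel$half_width > 0) convolve_image(ideal, kernel) else ideal
  if (noise_sd > 0) v <- v * (1 + matrix(stats::rnorm(length(v), 0, noise_sd),
                                         nrow(v)))
  v <- pmin(pmax(v, 0), 65535)
  matrix(as.integer(round(65535 - v)), nrow(v))
}

#' Generate the threshold-calibration box series
#'
#' Ideal square box fluences at the four nominal calibration sizes,
#' optionally blurred and inverted to raw frames.
#'
#' @param sizes_cm Box side lengths in cm (default 5, 10, 15, 20).
#' @param geometry A [detector_geometry()].
#' @param blur_sigma Gaussian scatter sigma in pixels (0 = no blur).
#' @param plateau Ideal in-field intensity (of 65535).
#' @return List with `raw` (list of [raw_frame()]), `ideal` (list of
#'   [fluence_image()] stage `"ideal"`), `sizes_cm`.
#' @export
gen_box_series <- function(sizes_cm = c(5, 10, 15, 20),
                           geometry = detector_geometry(),
                           blur_sigma = 2, plateau = 40000) {
  kernel <- if (blur_sigma > 0) gaussian_kernel(blur_sigma) else delta_kernel()
  ideal <- lapply(sizes_cm, function(s) {
    fluence_image(rasterize_box(s * 10, geometry, plateau), stage = "ideal")
  })
  raw <- lapply(seq_along(sizes_cm), function(k) {
    raw_frame(fluence_to_raw(ideal[[k]]$values, kernel), k - 1L, 0.3 * (k - 1))
  })
  list(raw = raw, ideal = ideal, sizes_cm = sizes_cm)
}

#' Build a synthetic sliding-window VMAT arc plan
#'
#' A deliverable toy arc: a rectangular sliding window whose center sweeps
#' the cross-plane axis while a per-leaf staircase modulates the edges. All
#' edge positions land on the detector pixel grid so rasterization is exact.
#'
#' @param n_cp Number of control points.
#' @param n_pairs Number of leaf pairs.
#' @param leaf_width_mm Width of every pair in mm.
#' @param total_mu Arc meterset.
#' @param gantry_start,gantry_end Arc limits in degrees (monotone sweep).
#' @param window_mm Cross-plane width of the sliding window.
#' @param sweep_mm Half-range of the window-center sweep.
#' @param stair_mm Amplitude of the per-leaf staircase offset.
#' @param dose_rate_waveform Function of arc fraction in `[0,1]` returning a
#'   relative dose rate (> 0); cumulative MU follows its integral.
#' @param collimator_angle Collimator angle (constant over the arc).
#' @return A [vmat_plan()].
#' @export
synthetic_arc_plan <- function(n_cp = 91, n_pairs = 20, leaf_width_mm = 5,
                               total_mu = 200, gantry_start = 180,
                               gantry_end = 480, window_mm = 30,
                               sweep_mm = 30, stair_mm = 2.5,
                               dose_rate_waveform = function(s) 1 + 0.5 * sin(2 * pi * s),
                               collimator_angle = 0) {
  s <- seq(0, 1, length.out = n_cp)
  rate <- vapply(s, dose_rate_waveform, 0)
  if (any(rate <= 0)) stop("dose-rate waveform must stay positive")
  # cumulative MU by trapezoidal integral of the rate, scaled to total_mu
  cum <- c(0, cumsum((rate[-1] + rate[-n_cp]) / 2 * diff(s)))
  cum <- total_mu * cum / cum[n_cp]
  gantry <- (gantry_start + s * (gantry_end - gantry_start)) %% 360
  stair <- stair_mm * ((seq_len(n_pairs) %% 4) - 1.5)  # -3.75..+3.75 pattern
  cps <- lapply(seq_len(n_cp), function(k) {
    center <- -sweep_mm + 2 * sweep_mm * s[k]
    left <- round((center - window_mm / 2 + stair) * 2) / 2
    right <- round((center + window_mm / 2 - stair) * 2) / 2
    plan_control_point(k - 1L, gantry[k], collimator_angle, cum[k],
                       left, right)
  })
  vmat_plan("synthetic-arc", "6", cps, rep(leaf_width_mm, n_pairs))
}

#' Generate a synthetic VMAT acquisition with ground truth
#'
#' Samples the arc at `n_frames` uniform time steps, rasterizes the true
#' aperture of each frame, blurs, adds optional multiplicative Gaussian
#' noise, and inverts to 16-bit raw frames. Frames emulate an
#' acquisition-normalized export: the in-field plateau is dose-independent
#' and the per-frame pixel scaling factor carries the dose scale, defined as
#' (in-field mean of the blurred processed image) / (true frame MU), so the
#' MU conversion is exact on noiseless frames. Frame apertures and gantry
#' angles are interpolated from the plan at the frame's arc fraction, with
#' aperture edges snapped to the pixel grid (the recorded truth is the
#' snapped aperture).
#'
#' @param plan A [vmat_plan()] (e.g. [synthetic_arc_plan()]).
#' @param n_frames Number of frames (>= 2).
#' @param geometry A [detector_geometry()].
#' @param blur_sigma Gaussian scatter sigma in pixels.
#' @param noise_sd Multiplicative noise SD (fraction; 0 = off).
#' @param offsets Optional injected [measure_center_offsets()] model; each
#'   frame is shifted by the model interpolated at its pose.
#' @param frame_period_s Seconds between frames.
#' @param plateau In-field raw-frame intensity (constant across frames).
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @return List of class `synthetic_acquisition`: `frames`, `log`
#'   (acquisition sidecar), `plan`, `truth` (per-frame true leaf positions,
#'   MU increments, gantry angles; plus `blur_sigma`, `noise_sd`, `seed`).
#' @export
gen_vmat_acquisition <- function(plan, n_frames = 60,
                                 geometry = detector_geometry(),
                                 blur_sigma = 2, noise_sd = 0, offsets = NULL,
                                 frame_period_s = 0.3, plateau = 40000,
                                 seed = 1L) {
  if (n_frames < 2) stop("need at least 2 frames")
  kernel <- if (blur_sigma > 0) gaussian_kernel(blur_sigma) else delta_kernel()
  set.seed(seed)
  cps <- plan$control_points
  cum <- vapply(cps, `[[`, 0, "cumulative_mu")
  if (any(diff(cum) <= 0)) stop("plan cumulative MU must be increasing")
  gantry <- vapply(cps, `[[`, 0, "gantry_angle")
  g_un <- gantry + 360 * cumsum(c(0, abs(diff(gantry)) > 180) *
                                  sign(c(0, -diff(gantry))))
  # Frames are uniform in time; with uniform gantry speed the frame grid is
  # uniform in arc fraction s. Frame k spans s in ((k-1)/n, k/n], delivers
  # the MU of that interval (shaped by the plan's dose-rate waveform via its
  # cumulative-MU curve), and shows the aperture at the interval midpoint.
  cp_s <- seq(0, 1, length.out = length(cps))
  s_edges <- seq(0, 1, length.out = n_frames + 1)
  mu_edges <- stats::approx(cp_s, cum, xout = s_edges)$y
  mu_inc <- diff(mu_edges)
  if (sum(mu_inc) <= 0) stop("dose waveform with zero total")
  s_mid <- (s_edges[-1] + s_edges[-(n_frames + 1)]) / 2
  banks_at <- function(s) {
    i <- findInterval(s, cp_s, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(cum) - 1L)
    w <- (s - cp_s[i]) / (cp_s[i + 1] - cp_s[i])
    left <- (1 - w) * cps[[i]]$bank_A + w * cps[[i + 1]]$bank_A
    right <- (1 - w) * cps[[i]]$bank_B + w * cps[[i + 1]]$bank_B
    # snap to the pixel grid: this *is* the recorded truth
    list(left = round(left / geometry$pixel_mm) * geometry$pixel_mm,
         right = round(right / geometry$pixel_mm) * geometry$pixel_mm)
  }
  frames <- vector("list", n_frames)
  psf <- numeric(n_frames)
  truth_left <- truth_right <- matrix(0, n_frames, plan$n_leaf_pairs)
  truth_g <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    bk <- banks_at(s_mid[k])
    truth_left[k, ] <- bk$left
    truth_right[k, ] <- bk$right
    truth_g[k] <- stats::approx(cp_s, g_un, xout = s_edges[k + 1])$y %% 360
    shift <- c(col = 0, row = 0)
    if (!is.null(offsets)) {
      cr <- pose_cross_offsets(offsets, truth_g[k],
                               cps[[1]]$collimator_angle)
      shift <- c(col = mean(cr), row = pose_in_offset(offsets, truth_g[k],
                                                      cps[[1]]$collimator_angle))
    }
    # the acquisition normalizes every raw frame to the 16-bit range, so the
    # plateau is dose-independent; the PSF carries the per-frame dose scale
    ideal <- rasterize_aperture(bk$left + shift["col"] * geometry$pixel_mm,
                                bk$right + shift["col"] * geometry$pixel_mm,
                                plan$leaf_widths, geometry, plateau = plateau)
    if (shift["row"] != 0) {
      r <- as.integer(round(shift["row"]))
      ideal <- shift_rows(ideal, r)
    }
    raw <- fluence_to_raw(ideal, kernel, noise_sd)
    frames[[k]] <- raw_frame(raw, k - 1L, frame_period_s * (k - 1))
    processed <- 65535 - raw
    infield <- ideal > 0
    psf[k] <- mean(processed[infield]) / mu_inc[k]
  }
  log <- acquisition_log(frame_period_s * (seq_len(n_frames) - 1), psf)
  truth <- list(left_mm = truth_left, right_mm = truth_right,
                mu_increment = mu_inc, gantry_deg = truth_g,
                collimator_deg = cps[[1]]$collimator_angle,
                blur_sigma = blur_sigma, noise_sd = noise_sd, seed = seed)
  structure(list(frames = frames, log = log, plan = plan, truth = truth,
                 geometry = geometry),
            class = "synthetic_acquisition")
}

shift_rows <- function(img, r) {
  if (r == 0) return(img)
  n <- nrow(img)
  out <- matrix(0, n, ncol(img))
  if (r > 0) out[(1 + r):n, ] <- img[1:(n - r), ]
  else out[1:(n + r), ] <- img[(1 - r):n, ]
  out
}

#' Generate the offset-calibration image sets
#'
#' 10 x 10 cm box images over the gantry-sag grid (10-degree steps,
#' collimator 0) and the collimator-shift grid (30 x 30 degree grid), each
#' shifted by the injected offset model at its pose. Feeding the result to
#' [measure_center_offsets()] should recover the injected model.
#'
#' @param injected An `offset_model` (e.g. [zero_offset_model()] modified in
#'   place) giving the shift in pixels at each pose.
#' @param geometry A [detector_geometry()].
#' @param blur_sigma Optional Gaussian blur in pixels.
#' @return List with `sag_images` and `coll_images` named as
#'   [measure_center_offsets()] expects, plus the grids.
#' @export
gen_offset_acquisition <- function(injected = zero_offset_model(),
                                   geometry = detector_geometry(),
                                   blur_sigma = 0) {
  kernel <- if (blur_sigma > 0) gaussian_kernel(blur_sigma) else delta_kernel()
  n <- geometry$resolution
  half <- 50 / geometry$pixel_mm  # 10 cm box
  # bank-specific sag moves each field edge by its own offset; the
  # collimator term shifts the whole field center
  mk <- function(left_off, right_off, top_off, bottom_off) {
    c0 <- as.integer(round(n / 2 - half + left_off))
    c1 <- as.integer(round(n / 2 + half + right_off))
    r0 <- as.integer(round(n / 2 - half + top_off))
    r1 <- as.integer(round(n / 2 + half + bottom_off))
    if (c0 < 0 || r0 < 0 || c1 > n || r1 > n) stop("box exceeds detector")
    v <- matrix(0, n, n)
    v[(r0 + 1L):r1, (c0 + 1L):c1] <- 40000
    if (kernel$half_width > 0) v <- convolve_image(v, kernel)
    v
  }
  at_pose <- function(g, cc) {
    ccx <- interp_coll(injected, injected$coll_shift_cross, g, cc)
    cci <- interp_coll(injected, injected$coll_shift_in, g, cc)
    mk(interp_gantry(injected$gantry_grid, injected$sag_cross_left, g) + ccx,
       interp_gantry(injected$gantry_grid, injected$sag_cross_right, g) + ccx,
       interp_gantry(injected$gantry_grid, injected$sag_in_upper, g) + cci,
       interp_gantry(injected$gantry_grid, injected$sag_in_lower, g) + cci)
  }
  sag <- list()
  for (g in injected$gantry_grid) sag[[sprintf("g%g", g)]] <- at_pose(g, 0)
  coll <- list()
  for (g in injected$coll_gantry_grid) {
    for (cc in injected$coll_grid) {
      coll[[sprintf("g%g_c%g", g, cc)]] <- at_pose(g, cc)
    }
  }
  list(sag_images = sag, coll_images = coll,
       gantry_grid = injected$gantry_grid,
       coll_gantry_grid = injected$coll_gantry_grid,
       coll_grid = injected$coll_grid)
}
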