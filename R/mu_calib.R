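#' Convert a processed frame to its MU-equivalent value
#'
#' Divides the in-field intensity of the processed (dose-proportional) image
#' by the frame's pixel scaling factor (PSF). The scalar statistic is the
#' mean pixel value inside the open field, taken from the frame's binary
#' aperture (robust to aperture size); a `"sum"` statistic is available.
#'
#' @param processed A [fluence_image()] with `stage = "processed"`.
#' @param psf Positive per-frame pixel scaling factor.
#' @param aperture A [binarize()] result defining field membership.
#' @param stat `"mean"` (default) or `"sum"`.
#' @return Scalar MU-equivalent value (0 with a warning if the aperture is
#'   empty).
#' @export
frame_mu <- function(processed, psf, aperture, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  stopifnot(inherits(processed, "fluence_image"),
            inherits(aperture, "binary_aperture"))
  if (processed$stage != "processed") stop("frame_mu expects a processed image")
  if (psf <= 0) stop("psf must be > 0")
  if (!any(aperture$mask)) {
    warning("empty aperture: MU-equivalent set to 0")
    return(0)
  }
  v <- processed$values[aperture$mask]
  (if (stat == "mean") mean(v) else sum(v)) / psf
}

#' MU linearity and dose-rate independence check
#'
#' Fits a least-squares line through (delivered MU, measured MU-equivalent)
#' points and summarizes the spread of a fixed-MU series delivered at
#' different dose rates, mirroring the commissioning checks performed with
#' open 10 x 10 cm fields.
#'
#' @param delivered_mu Delivered MU levels (>= 3).
#' @param measured Measured MU-equivalent values, same length.
#' @param dose_rates Optional dose rates (MU/min) of a fixed-MU series (>= 2).
#' @param dose_rate_measured MU-equivalents of the fixed-MU series.
#' @return An object of class `linearity_report`: `points`, `slope`,
#'   `intercept`, `r_squared`, `dose_rate_points`, `max_rel_spread`.
#' @export
check_linearity <- function(delivered_mu, measured, dose_rates = NULL,
                            dose_rate_measured = NULL) {
  if (length(delivered_mu) < 3) stop("need at least 3 MU levels")
  if (length(delivered_mu) != length(measured)) stop("length mismatch")
  fit <- stats::lm(measured ~ delivered_mu)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((measured - mean(measured))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  spread <- NA_real_
  drp <- NULL
  if (!is.null(dose_rates)) {
    if (length(dose_rates) < 2 || length(dose_rates) != length(dose_rate_measured)) {
      stop("need >= 2 dose-rate points with matching measurements")
    }
    spread <- (max(dose_rate_measured) - min(dose_rate_measured)) /
      mean(dose_rate_measured)
    drp <- data.frame(dose_rate = dose_rates, measured = dose_rate_measured)
  }
  structure(list(points = data.frame(delivered_mu = delivered_mu,
                                     measured = measured),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 dose_rate_points = drp,
                 max_rel_spread = spread),
            class = "linearity_report")
}

#' Assign cumulative MU and gantry angle to each frame
#'
#' Normalizes the per-frame MU-equivalents so their running sum projects
#' onto the plan's total MU exactly, then assigns each frame a gantry angle
#' by inverse interpolation of the plan's cumulative-MU-vs-gantry polyline
#' (the plan's spatially uniform control points generally outnumber or
#' undernumber the temporally uniform frames, so this mapping is how the two
#' samplings are reconciled). The collimator angle is copied from the plan
#' (constant per arc).
#'
#' @param mu_equiv Per-frame MU-equivalent values from [frame_mu()].
#' @param plan A [vmat_plan()] whose cumulative MU is strictly increasing.
#' @param log An [acquisition_log()] supplying frame times.
#' @param angle_map `"mu"` (inverse MU interpolation, default) or `"time"`
#'   (linear in timestamp across the arc).
#' @return A data.frame with `frame_index`, `time_s`, `gantry_deg`,
#'   `collimator_deg`, `cumulative_mu`.
#' @export
assign_frame_records <- function(mu_equiv, plan, log,
                                 angle_map = c("mu", "time")) {
  angle_map <- match.arg(angle_map)
  if (length(mu_equiv) != log$n_frames) stop("frame count mismatch with log")
  total_equiv <- sum(mu_equiv)
  if (total_equiv <= 0) stop("zero total MU-equivalent")
  cum_mu <- plan$total_mu * cumsum(mu_equiv) / total_equiv
  plan_mu <- vapply(plan$control_points, `[[`, 0, "cumulative_mu")
  if (any(diff(plan_mu) <= 0)) {
    stop("plan cumulative MU must be strictly increasing for angle mapping")
  }
  plan_g <- vapply(plan$control_points, `[[`, 0, "gantry_angle")
  # unwrap gantry across the 0/360 seam so interpolation is monotone
  g_un <- plan_g + 360 * cumsum(c(0, abs(diff(plan_g)) > 180) *
                                  sign(c(0, -diff(plan_g))))
  if (angle_map == "mu") {
    gantry <- stats::approx(plan_mu, g_un, xout = cum_mu, rule = 2)$y %% 360
  } else {
    tt <- log$frame_times
    frac <- if (max(tt) > min(tt)) (tt - min(tt)) / (max(tt) - min(tt)) else 1
    gantry <- (g_un[1] + frac * (g_un[length(g_un)] - g_un[1])) %% 360
  }
  data.frame(frame_index = seq_along(mu_equiv) - 1L,
             time_s = log$frame_times,
             gantry_deg = gantry,
             collimator_deg = plan$control_points[[1]]$collimator_angle,
             cumulative_mu = cum_mu)
}
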