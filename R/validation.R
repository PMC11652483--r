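#' Compare an extracted log against synthetic ground truth
#'
#' Aggregates per-frame, per-leaf absolute position errors (in detector
#' pixels), per-frame MU increment errors and gantry-angle errors.
#'
#' @param acq A [gen_vmat_acquisition()] result (carries the truth).
#' @param log An [epid_log()] produced from the same frames.
#' @return An object of class `recovery_report`: `leaf_rmse_px`,
#'   `leaf_max_err_px`, `mu_rel_err` (max relative error of per-frame MU
#'   increments), `gantry_max_err_deg`, `n_frames`.
#' @export
recover <- function(acq, log) {
  stopifnot(inherits(acq, "synthetic_acquisition"), inherits(log, "epid_log"))
  n <- length(acq$frames)
  if (nrow(log$records) != n) stop("frame count mismatch between truth and log")
  px <- acq$geometry$pixel_mm
  open <- acq$truth$right_mm > acq$truth$left_mm
  errs <- c((log$bank_A - acq$truth$left_mm)[open],
            (log$bank_B - acq$truth$right_mm)[open]) / px
  inc <- diff(c(0, log$records$cumulative_mu))
  true_inc <- acq$truth$mu_increment
  mu_rel <- max(abs(inc - true_inc) / max(true_inc))
  dg <- abs(log$records$gantry_deg - acq$truth$gantry_deg)
  dg <- pmin(dg, 360 - dg)
  structure(list(leaf_rmse_px = sqrt(mean(errs^2)),
                 leaf_max_err_px = max(abs(errs)),
                 mu_rel_err = mu_rel,
                 gantry_max_err_deg = max(dg),
                 n_frames = n),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("<recovery_report> %d frames | leaf RMSE %.3f px (max ",
                     "%.3f) | MU rel err %.2e | gantry max err %.3f deg\n"),
              x$n_frames, x$leaf_rmse_px, x$leaf_max_err_px, x$mu_rel_err,
              x$gantry_max_err_deg))
  invisible(x)
}

#' 2D global gamma comparison
#'
#' Low-style gamma index between a reference and an evaluated fluence with
#' global dose normalization: for every reference pixel at or above
#' `low_dose_cut` of the reference maximum,
#' `gamma^2 = min_d [ |d|^2/dta^2 + (E(r+d) - R(r))^2 / (dd * Rmax)^2 ]`
#' over displacements `d` on a `step_px` grid within `3 * dta`. The
#' evaluated image is sampled bilinearly. Passing means `gamma <= 1`.
#'
#' @param reference,evaluated [fluence_image()]s (or matrices) of identical
#'   shape.
#' @param dd_percent Dose-difference criterion, percent of the reference max.
#' @param dta_mm Distance-to-agreement criterion in mm.
#' @param low_dose_cut Fraction of the reference max below which reference
#'   pixels are excluded.
#' @param pixel_mm Pixel pitch in mm.
#' @param step_px Displacement search step in pixels.
#' @return An object of class `gamma_result`: `gpr` (percent), `dd_percent`,
#'   `dta_mm`, `low_dose_cut`, `n_evaluated`.
#' @export
gamma_2d <- function(reference, evaluated, dd_percent = 3, dta_mm = 3,
                     low_dose_cut = 0.10, pixel_mm = 0.5, step_px = 0.1) {
  R <- if (inherits(reference, "fluence_image")) reference$values else reference
  E <- if (inherits(evaluated, "fluence_image")) evaluated$values else evaluated
  if (!identical(dim(R), dim(E))) stop("shape mismatch")
  rmax <- max(R)
  if (rmax <= 0) stop("reference image is empty")
  sel <- R >= low_dose_cut * rmax
  if (!any(sel)) stop("all reference pixels below the low-dose cutoff")
  dta_px <- dta_mm / pixel_mm
  dnorm_ <- dd_percent / 100 * rmax
  # displacement grid within 3*dta, sorted by |d| so the search can stop
  # once the spatial term alone exceeds the worst remaining gamma
  radius <- 3 * dta_px
  steps <- seq(-floor(radius / step_px), floor(radius / step_px)) * step_px
  grid <- expand.grid(dx = steps, dy = steps)
  grid <- grid[grid$dx^2 + grid$dy^2 <= radius^2, ]
  grid <- grid[order(grid$dx^2 + grid$dy^2), ]
  nr <- nrow(R); nc <- ncol(R)
  ri <- row(R)[sel]; ci <- col(R)[sel]
  refv <- R[sel]
  g2 <- rep(Inf, length(refv))
  for (k in seq_len(nrow(grid))) {
    s2 <- (grid$dx[k]^2 + grid$dy[k]^2) / dta_px^2
    if (s2 >= max(g2)) break
    y <- ri + grid$dy[k]; x <- ci + grid$dx[k]
    inb <- y >= 1 & y <= nr & x >= 1 & x <= nc  # displaced samples outside
    y0 <- floor(y); x0 <- floor(x)              # the image are unavailable
    wy <- y - y0; wx <- x - x0
    y0 <- pmin(pmax(y0, 1L), nr); y1 <- pmin(y0 + 1L, nr)
    x0 <- pmin(pmax(x0, 1L), nc); x1 <- pmin(x0 + 1L, nc)
    ev <- (1 - wy) * ((1 - wx) * E[cbind(y0, x0)] + wx * E[cbind(y0, x1)]) +
      wy * ((1 - wx) * E[cbind(y1, x0)] + wx * E[cbind(y1, x1)])
    cand <- s2 + ((ev - refv) / dnorm_)^2
    cand[!inb] <- Inf
    g2 <- pmin(g2, cand)
  }
  structure(list(gpr = 100 * mean(g2 <= 1), dd_percent = dd_percent,
                 dta_mm = dta_mm, low_dose_cut = low_dose_cut,
                 n_evaluated = length(refv)),
            class = "gamma_result")
}

#' Summary statistics of the 18-plan gamma passing rate table
#'
#' Mean and sample SD of the proposed-method gamma passing rate, the number
#' of plans below the 90% clinical action level, and the Spearman
#' correlation between the proposed and machine-log passing rates, overall
#' and restricted to the 6 MV (non-FFF) plans.
#'
#' @param table A [read_table3()] data.frame.
#' @return Named list: `mean_gpr`, `sd_gpr`, `n_below_90`, `rho_all`,
#'   `rho_6mv`, `p_all`, `p_6mv`.
#' @export
reproduce_table3_stats <- function(table = read_table3()) {
  if (nrow(table) != 18) stop("expected the 18-plan table")
  s_all <- spearman(table$gpr_prop, table$gpr_mach)
  six <- table$beam == "6"
  s_6 <- spearman(table$gpr_prop[six], table$gpr_mach[six])
  list(mean_gpr = mean(table$gpr_prop),
       sd_gpr = stats::sd(table$gpr_prop),
       n_below_90 = sum(table$gpr_prop < 90),
       rho_all = s_all$rho, p_all = s_all$p_value,
       rho_6mv = s_6$rho, p_6mv = s_6$p_value)
}
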