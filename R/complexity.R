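## Plan complexity indices for VMAT arcs.
##
## The six indices follow the McNiven modulation-complexity family as
## extended to VMAT (MCSv) plus the common leaf-travel and small-aperture
## scores: per control point a leaf sequence variability (LSV) and aperture
## area variability (AAV) are computed over the in-field leaf pairs, then
## combined across the arc with MU weighting. "In-field" pairs are those
## whose aperture opens at any control point of the arc.

infield_pairs <- function(plan) {
  open_any <- rep(FALSE, plan$n_leaf_pairs)
  for (cp in plan$control_points) open_any <- open_any | (cp$bank_B > cp$bank_A)
  which(open_any)
}

#' Leaf sequence variability of one control point
#'
#' Per bank, with `pos_max = max(pos) - min(pos)` over the `N` in-field
#' leaves: `LSV = sum_{n=1}^{N-1} (pos_max - |pos_n - pos_{n+1}|) /
#' ((N-1) * pos_max)`; a bank with `pos_max = 0` (all leaves aligned)
#' contributes 1. The control point value is the product of the two banks.
#'
#' @param cp A [plan_control_point()].
#' @param pairs Indices of in-field leaf pairs (default: pairs open at this
#'   control point's arc; pass the arc-level set for plan indices).
#' @return LSV in `[0, 1]`.
#' @export
leaf_sequence_variability <- function(cp, pairs = which(cp$bank_B > cp$bank_A)) {
  if (length(pairs) < 2) {
    warning("fewer than 2 in-field leaf pairs: LSV = 1")
    return(1)
  }
  bank_lsv <- function(pos) {
    pmax_ <- max(pos) - min(pos)
    if (pmax_ == 0) return(1)
    d <- abs(diff(pos))
    sum(pmax_ - d) / ((length(pos) - 1) * pmax_)
  }
  bank_lsv(cp$bank_A[pairs]) * bank_lsv(cp$bank_B[pairs])
}

#' Aperture area variability of one control point
#'
#' Ratio of the control point's total opening to the total of the per-pair
#' maximum openings over the whole arc:
#' `AAV = sum_n (B_n - A_n) / sum_n max_opening_n` (0 when the denominator
#' vanishes).
#'
#' @param cp A [plan_control_point()].
#' @param arc_max_apertures Per-pair maximum opening (mm) over all control
#'   points of the arc, for the same pair set as the banks.
#' @return AAV in `[0, 1]`.
#' @export
aperture_area_variability <- function(cp, arc_max_apertures) {
  gap <- cp$bank_B - cp$bank_A
  if (any(gap < 0)) stop("negative aperture opening")
  denom <- sum(arc_max_apertures)
  if (denom <= 0) return(0)
  sum(gap) / denom
}

arc_max_openings <- function(plan, pairs) {
  apply(vapply(plan$control_points,
               function(cp) (cp$bank_B - cp$bank_A)[pairs],
               numeric(length(pairs))), 1, max)
}

per_cp_lsv_aav <- function(plan) {
  pairs <- infield_pairs(plan)
  mx <- arc_max_openings(plan, pairs)
  lsv <- vapply(plan$control_points, leaf_sequence_variability,
                0, pairs = pairs)
  aav <- vapply(plan$control_points, function(cp) {
    sub <- plan_control_point(cp$index, cp$gantry_angle, cp$collimator_angle,
                              cp$cumulative_mu, cp$bank_A[pairs],
                              cp$bank_B[pairs])
    aperture_area_variability(sub, mx)
  }, 0)
  list(lsv = lsv, aav = aav, pairs = pairs)
}

#' Modulation complexity score for VMAT
#'
#' MU-weighted product of segment-averaged AAV and LSV over consecutive
#' control point pairs:
#' `MCSv = sum_cp ((AAV_cp + AAV_cp+1)/2) * ((LSV_cp + LSV_cp+1)/2) *
#' dMU_cp / MU_total`. An unmodulated constant-aperture sweep scores 1;
#' heavier modulation drives the score toward 0.
#'
#' @param plan A [vmat_plan()].
#' @return MCSv in `(0, 1]`.
#' @export
mcsv <- function(plan) {
  if (plan$total_mu <= 0) stop("plan has zero total MU")
  pc <- per_cp_lsv_aav(plan)
  mu <- vapply(plan$control_points, `[[`, 0, "cumulative_mu")
  dmu <- diff(mu)
  k <- seq_along(dmu)
  sum((pc$aav[k] + pc$aav[k + 1]) / 2 *
      (pc$lsv[k] + pc$lsv[k + 1]) / 2 * dmu) / plan$total_mu
}

#' Mean leaf travel
#'
#' Total absolute leaf displacement across the arc averaged over the moving
#' leaves (both banks of the in-field pairs):
#' `LT = sum_leaves sum_transitions |dpos| / N_leaves` (mm).
#'
#' @param plan A [vmat_plan()].
#' @return Mean per-leaf travel in mm.
#' @export
leaf_travel <- function(plan) {
  pairs <- infield_pairs(plan)
  a <- vapply(plan$control_points, function(cp) cp$bank_A[pairs],
              numeric(length(pairs)))
  b <- vapply(plan$control_points, function(cp) cp$bank_B[pairs],
              numeric(length(pairs)))
  a <- matrix(a, nrow = length(pairs)); b <- matrix(b, nrow = length(pairs))
  travel <- sum(abs(t(diff(t(a))))) + sum(abs(t(diff(t(b)))))
  travel / (2 * length(pairs))
}

#' Small aperture score
#'
#' MU-weighted fraction of open leaf pairs whose gap is below
#' `gap_threshold_mm`, averaged over consecutive control points with the
#' same segment MU weights as [mcsv()].
#'
#' @param plan A [vmat_plan()].
#' @param gap_threshold_mm Gap defining a "small" aperture (default 10 mm).
#' @return SAS in `[0, 1]`.
#' @export
small_aperture_score <- function(plan, gap_threshold_mm = 10) {
  if (plan$total_mu <= 0) stop("plan has zero total MU")
  f <- vapply(plan$control_points, function(cp) {
    gap <- cp$bank_B - cp$bank_A
    open <- gap > 0
    if (!any(open)) return(0)
    mean(gap[open] < gap_threshold_mm)
  }, 0)
  mu <- vapply(plan$control_points, `[[`, 0, "cumulative_mu")
  dmu <- diff(mu)
  k <- seq_along(dmu)
  sum((f[k] + f[k + 1]) / 2 * dmu) / plan$total_mu
}

#' Leaf-travel weighted modulation complexity score
#'
#' `LTMCS = MCSv * max(0, 1 - LT / lt_norm_mm)`; `lt_norm_mm` is the travel
#' scale at which the weight reaches zero.
#'
#' @param plan A [vmat_plan()].
#' @param lt_norm_mm Normalization constant in mm (default 500).
#' @return LTMCS in `[0, 1]`.
#' @export
ltmcs <- function(plan, lt_norm_mm = 500) {
  mcsv(plan) * max(0, 1 - leaf_travel(plan) / lt_norm_mm)
}

#' MLC / MU transition metrics
#'
#' For each pair of consecutive control points, computes the mean and the
#' maximum absolute leaf displacement over the in-field leaves (both banks)
#' and the MU increment; reports the mean and sample standard deviation of
#' each across transitions (SD reported as 0 for a single transition).
#'
#' @param plan A [vmat_plan()].
#' @return Named list: `mlc_mn`, `mlc_sn` (mean/SD of per-transition mean
#'   travel, mm), `mlc_mx`, `mlc_sx` (same for max travel), `mu_mean`,
#'   `mu_std` (MU).
#' @export
transition_metrics <- function(plan) {
  pairs <- infield_pairs(plan)
  cps <- plan$control_points
  n_tr <- length(cps) - 1L
  mean_tr <- max_tr <- dmu <- numeric(n_tr)
  for (k in seq_len(n_tr)) {
    d <- c(abs(cps[[k + 1]]$bank_A[pairs] - cps[[k]]$bank_A[pairs]),
           abs(cps[[k + 1]]$bank_B[pairs] - cps[[k]]$bank_B[pairs]))
    mean_tr[k] <- mean(d)
    max_tr[k] <- max(d)
    dmu[k] <- cps[[k + 1]]$cumulative_mu - cps[[k]]$cumulative_mu
  }
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  list(mlc_mn = mean(mean_tr), mlc_sn = sd0(mean_tr),
       mlc_mx = mean(max_tr), mlc_sx = sd0(max_tr),
       mu_mean = mean(dmu), mu_std = sd0(dmu))
}

#' Full complexity report for one plan
#'
#' @param plan A [vmat_plan()].
#' @param gap_threshold_mm Small-aperture gap threshold (mm).
#' @param lt_norm_mm Leaf-travel normalization for LTMCS (mm).
#' @return An object of class `plan_complexity`: the six complexity indices
#'   (`sas`, `lt`, `mcsv`, `ltmcs`, `aav`, `lsv` -- the latter two MU-weighted
#'   arc averages) and the six transition metrics.
#' @export
plan_complexity <- function(plan, gap_threshold_mm = 10, lt_norm_mm = 500) {
  pc <- per_cp_lsv_aav(plan)
  mu <- vapply(plan$control_points, `[[`, 0, "cumulative_mu")
  dmu <- diff(mu)
  k <- seq_along(dmu)
  w_avg <- function(v) sum((v[k] + v[k + 1]) / 2 * dmu) / plan$total_mu
  out <- c(list(sas = small_aperture_score(plan, gap_threshold_mm),
                lt = leaf_travel(plan),
                mcsv = mcsv(plan),
                ltmcs = ltmcs(plan, lt_norm_mm),
                aav = w_avg(pc$aav),
                lsv = w_avg(pc$lsv)),
           transition_metrics(plan))
  structure(out, class = "plan_complexity")
}

#' @export
print.plan_complexity <- function(x, ...) {
  cat("<plan_complexity>\n")
  cat(sprintf("  SAS %.3f | LT %.1f mm | MCSv %.3f | LTMCS %.3f | AAV %.3f | LSV %.3f\n",
              x$sas, x$lt, x$mcsv, x$ltmcs, x$aav, x$lsv))
  cat(sprintf("  MLC mean %.2f+/-%.2f mm, max %.2f+/-%.2f mm | dMU %.2f+/-%.2f\n",
              x$mlc_mn, x$mlc_sn, x$mlc_mx, x$mlc_sx, x$mu_mean, x$mu_std))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling; the coefficient is the
#' Pearson correlation of the ranks and the p-value uses the t
#' approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 4`.
#' @return An object of class `correlation_result`: `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 4) stop("need at least 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "correlation_result")
}

#' Correlate gamma passing rate with the complexity indices
#'
#' Runs [spearman()] between the proposed-method gamma passing rate and each
#' of the other 13 columns of the 18-plan table. Three indices (SAS, LSV,
#' LT) correlated opposite to their usual complexity interpretation in the
#' source data and are flagged `excluded` from significance claims; they are
#' still computed.
#'
#' @param table A [read_table3()] data.frame.
#' @return data.frame with `metric`, `rho`, `p_value`, `excluded`.
#' @export
correlate_table3 <- function(table) {
  metrics <- c("gpr_mach", "sas", "mcsv", "lt", "ltmcs", "aav", "lsv",
               "mlc_mn", "mlc_sn", "mlc_mx", "mlc_sx", "mu_mean", "mu_std")
  excluded <- c("sas", "lsv", "lt")
  rows <- lapply(metrics, function(m) {
    s <- spearman(table$gpr_prop, table[[m]])
    data.frame(metric = m, rho = s$rho, p_value = s$p_value,
               excluded = m %in% excluded)
  })
  do.call(rbind, rows)
}
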