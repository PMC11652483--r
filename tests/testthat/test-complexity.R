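# hand-evaluated values for toy_plan(), frozen from a standalone
# transcription of the index definitions
test_that("toy arc indices match the hand-evaluated sums", {
  plan <- toy_plan()
  rep_ <- plan_complexity(plan)
  expect_equal(rep_$mcsv, 0.2114583333, tolerance = 1e-9)
  expect_equal(rep_$lt, 6.3333333333, tolerance = 1e-9)
  expect_equal(rep_$sas, 0)
  expect_equal(rep_$ltmcs, 0.2087798611, tolerance = 1e-9)
  expect_equal(rep_$mlc_mn, 3.1666666667, tolerance = 1e-9)
  expect_equal(rep_$mlc_sn, 2.3570226040, tolerance = 1e-9)
  expect_equal(rep_$mlc_mx, 4.5)
  expect_equal(rep_$mlc_sx, 3.5355339059, tolerance = 1e-9)
  expect_equal(rep_$mu_mean, 50)
  expect_equal(rep_$mu_std, 14.1421356237, tolerance = 1e-9)
  cp1 <- plan$control_points[[1]]
  expect_equal(leaf_sequence_variability(cp1), 0.25, tolerance = 1e-12)
  expect_equal(aperture_area_variability(cp1, c(20, 23, 29)), 1.0)
})

test_that("limit cases behave as the definitions demand", {
  # aligned banks: pos_max = 0 on both banks
  cp <- plan_control_point(0L, 0, 0, 1, rep(-5, 4), rep(5, 4))
  expect_equal(leaf_sequence_variability(cp), 1.0)
  # two-pair bank with positions {0, 10}
  cp2 <- plan_control_point(0L, 0, 0, 1, c(0, 10), c(20, 30))
  a_only <- function(p) { pm <- max(p) - min(p)
    sum(pm - abs(diff(p))) / ((length(p) - 1) * pm) }
  expect_equal(a_only(c(0, 10)), 0)
  # all-closed control point
  closed <- plan_control_point(0L, 0, 0, 1, rep(0, 3), rep(0, 3))
  expect_equal(aperture_area_variability(closed, rep(10, 3)), 0)
  # 2-CP toy arc openings 10,10 then 20,20
  cpA <- plan_control_point(0L, 0, 0, 0, c(-5, -5), c(5, 5))
  expect_equal(aperture_area_variability(cpA, c(20, 20)), 0.5)
  # static plan limits
  st <- static_plan()
  expect_equal(mcsv(st), 1.0)
  expect_equal(leaf_travel(st), 0)
  expect_equal(ltmcs(st), mcsv(st))
  # every gap below the threshold
  sm <- vmat_plan("small", "6", list(
    plan_control_point(0L, 0, 0, 0, c(-1, -1), c(1, 1)),
    plan_control_point(1L, 10, 0, 50, c(-1, -1), c(1, 1))), c(10, 10))
  expect_equal(small_aperture_score(sm, 10), 1.0)
  expect_error(mcsv(vmat_plan("z", "6", list(
    plan_control_point(0L, 0, 0, 0, -1, 1),
    plan_control_point(1L, 5, 0, 0, -1, 1)), 10)), "zero total MU")
})

test_that("unit-interval bounds hold across random synthetic plans", {
  set.seed(99)
  for (rep_i in 1:8) {
    n_cp <- sample(3:12, 1)
    n_pairs <- sample(3:10, 1)
    cps <- lapply(seq_len(n_cp), function(k) {
      a <- round(runif(n_pairs, -40, 0), 1)
      plan_control_point(k - 1L, (k - 1) %% 360, 0,
                         (k - 1) * runif(1, 5, 20),
                         a, a + round(runif(n_pairs, 0, 40), 1))
    })
    # enforce strictly increasing MU
    mu <- cumsum(runif(n_cp, 1, 10)); mu <- mu - mu[1]
    for (k in seq_len(n_cp)) cps[[k]]$cumulative_mu <- mu[k]
    plan <- vmat_plan("rand", "6", cps, rep(5, n_pairs))
    r <- plan_complexity(plan)
    expect_true(r$mcsv > 0 && r$mcsv <= 1)
    expect_true(r$aav > 0 && r$aav <= 1)
    expect_true(r$lsv >= 0 && r$lsv <= 1)
    expect_true(r$sas >= 0 && r$sas <= 1)
    expect_true(r$lt >= 0)
    expect_true(all(is.finite(unlist(r))))
  }
})

test_that("MCSv decreases as aperture modulation amplitude grows", {
  mk <- function(amp) {
    n_cp <- 20
    cps <- lapply(seq_len(n_cp), function(k) {
      jit <- amp * (k %% 2)
      plan_control_point(k - 1L, (k - 1) * 5, 0, (k - 1) * 10,
                         rep(-10 - jit, 6), rep(10 + jit, 6))
    })
    vmat_plan("jit", "6", cps, rep(5, 6))
  }
  vals <- vapply(c(0, 2, 5, 10, 20), function(a) mcsv(mk(a)), 0)
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 1)
})

test_that("transition metrics are invariant under arc reversal", {
  plan <- toy_plan()
  rev_cps <- rev(plan$control_points)
  for (k in seq_along(rev_cps)) {
    rev_cps[[k]]$index <- k - 1L
    rev_cps[[k]]$cumulative_mu <- plan$total_mu -
      plan$control_points[[length(rev_cps) - k + 1]]$cumulative_mu
  }
  rplan <- vmat_plan("rev", "6", rev_cps, plan$leaf_widths)
  expect_equal(transition_metrics(rplan)[c("mlc_mn", "mlc_sn", "mlc_mx", "mlc_sx")],
               transition_metrics(plan)[c("mlc_mn", "mlc_sn", "mlc_mx", "mlc_sx")])
  # degenerate single transition reports SD 0
  two <- vmat_plan("two", "6", list(
    plan_control_point(0L, 0, 0, 0, c(-10, -10), c(0, 0)),
    plan_control_point(1L, 10, 0, 10, c(-5, -5), c(5, 5))), c(10, 10))
  tm <- transition_metrics(two)
  expect_equal(unlist(tm), c(mlc_mn = 5, mlc_sn = 0, mlc_mx = 5, mlc_sx = 0,
                             mu_mean = 10, mu_std = 0))
})

test_that("spearman matches a brute-force rank transcription and its contract", {
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6)
    s <- spearman(x, y)
    # independent oracle: explicit average ranks + Pearson sum formula
    rk <- function(v) {
      sapply(seq_along(v), function(i) {
        mean(which(sort(v)[order(order(sort(v)))] == v[i]))
        })
    }
    rx <- rank(x); ry <- rank(y)
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(s$rho, num / den, tolerance = 1e-12)
    expect_equal(spearman(y, x)$rho, s$rho)
  }
  expect_equal(spearman(1:5, c(9, 7, 5, 3, 1))$rho, -1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:3, 1:3), "4 observations")
})

test_that("the 18-plan correlation table reproduces the published coefficients", {
  tab <- read_table3()
  res <- correlate_table3(tab)
  expect_equal(res$rho[res$metric == "gpr_mach"], 0.737, tolerance = 0.005)
  # frozen from the fixture itself (printed indices are 3-dp rounded, which
  # perturbs ranks slightly relative to the source analysis)
  expect_equal(res$rho[res$metric == "aav"], 0.534, tolerance = 2e-3)
  expect_equal(res$rho[res$metric == "mcsv"], 0.495, tolerance = 2e-3)
  expect_equal(res$rho[res$metric == "lsv"], -0.660, tolerance = 2e-3)
  expect_true(all(res$excluded[res$metric %in% c("sas", "lsv", "lt")]))
  expect_true(res$p_value[res$metric == "aav"] < 0.05)
})
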