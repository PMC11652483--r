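log_from_truth <- function(acq) {
  n <- length(acq$frames)
  rec <- data.frame(frame_index = seq_len(n) - 1L,
                    time_s = acq$log$frame_times,
                    gantry_deg = acq$truth$gantry_deg,
                    collimator_deg = acq$truth$collimator_deg,
                    cumulative_mu = cumsum(acq$truth$mu_increment))
  epid_log(rec, acq$truth$left_mm, acq$truth$right_mm,
           header = list(plan_id = acq$plan$plan_id))
}

test_that("recovery against the truth itself is all zeros", {
  acq <- quick_acq(n_frames = 3)
  rep_ <- recover(acq, log_from_truth(acq))
  expect_equal(rep_$leaf_rmse_px, 0)
  expect_equal(rep_$leaf_max_err_px, 0)
  expect_equal(rep_$mu_rel_err, 0)
  expect_equal(rep_$gantry_max_err_deg, 0)
  expect_equal(rep_$n_frames, 3)
})

test_that("a single perturbed leaf surfaces as the max error", {
  acq <- quick_acq(n_frames = 3)
  log <- log_from_truth(acq)
  open <- which(acq$truth$right_mm[2, ] > acq$truth$left_mm[2, ])
  log$bank_A[2, open[1]] <- log$bank_A[2, open[1]] + 2 * 0.5  # 2 px in mm
  rep_ <- recover(acq, log)
  expect_equal(rep_$leaf_max_err_px, 2)
  expect_lt(rep_$leaf_rmse_px, 2)
  short <- log; short$records <- short$records[1:2, ]
  short$bank_A <- short$bank_A[1:2, ]; short$bank_B <- short$bank_B[1:2, ]
  expect_error(recover(acq, short), "frame count mismatch")
})

test_that("gamma of an image with itself is 100 and scaling respects dd", {
  a <- matrix(0, 48, 48); a[12:36, 10:38] <- 100
  expect_equal(gamma_2d(a, a)$gpr, 100)
  expect_equal(gamma_2d(a, a * 1.029)$gpr, 100)  # within 3% everywhere
  expect_error(gamma_2d(a, matrix(0, 10, 10)), "shape")
  expect_error(gamma_2d(matrix(0, 4, 4), matrix(0, 4, 4)), "empty|cutoff")
})

test_that("optimized gamma equals an exhaustive per-pixel oracle", {
  set.seed(21)
  mk <- function() convolve_image(matrix(runif(64 * 64, 0, 100), 64),
                                  gaussian_kernel(2))
  R <- mk(); E <- R + convolve_image(matrix(rnorm(64 * 64, 0, 4), 64),
                                     gaussian_kernel(1.5))
  dd <- 3; dta_mm <- 1; pixel_mm <- 0.5; step <- 0.1; cut <- 0.10
  res <- gamma_2d(R, E, dd, dta_mm, cut, pixel_mm, step)
  # brute force: loop every reference pixel over the full displacement disc
  dta_px <- dta_mm / pixel_mm
  radius <- 3 * dta_px
  steps <- seq(-floor(radius / step), floor(radius / step)) * step
  grid <- expand.grid(dx = steps, dy = steps)
  grid <- grid[grid$dx^2 + grid$dy^2 <= radius^2, ]
  rmax <- max(R); dnorm_ <- dd / 100 * rmax
  sel <- which(R >= cut * rmax)
  pass <- logical(length(sel))
  s2 <- (grid$dx^2 + grid$dy^2) / dta_px^2
  for (ii in seq_along(sel)) {
    p <- sel[ii]
    yy <- (p - 1) %% 64 + 1; xx <- (p - 1) %/% 64 + 1
    y <- yy + grid$dy; x <- xx + grid$dx
    inb <- y >= 1 & y <= 64 & x >= 1 & x <= 64
    y0 <- pmin(pmax(floor(y), 1), 64); y1 <- pmin(y0 + 1, 64)
    x0 <- pmin(pmax(floor(x), 1), 64); x1 <- pmin(x0 + 1, 64)
    wy <- y - y0; wx <- x - x0
    ev <- (1 - wy) * ((1 - wx) * E[cbind(y0, x0)] + wx * E[cbind(y0, x1)]) +
      wy * ((1 - wx) * E[cbind(y1, x0)] + wx * E[cbind(y1, x1)])
    g2 <- s2 + ((ev - R[p]) / dnorm_)^2
    g2[!inb] <- Inf
    pass[ii] <- min(g2) <= 1
  }
  expect_equal(res$gpr, 100 * mean(pass))
  expect_equal(res$n_evaluated, length(sel))
})

test_that("gamma passing rate shrinks with tighter criteria", {
  set.seed(8)
  R <- convolve_image(matrix(runif(32 * 32, 0, 100), 32), gaussian_kernel(2))
  E <- R * 1.04 + 1.5
  prev <- -1
  for (crit in c(1, 2, 3, 5)) {
    g <- gamma_2d(R, E, dd_percent = crit, dta_mm = crit, pixel_mm = 1)$gpr
    expect_gte(g, prev)
    prev <- g
  }
})

test_that("the 18-plan table statistics reproduce the published summary", {
  s <- reproduce_table3_stats()
  expect_equal(round(s$mean_gpr, 1), 95.2)
  expect_equal(round(s$sd_gpr, 1), 3.7)
  expect_equal(s$n_below_90, 2)
  expect_equal(s$rho_all, 0.737, tolerance = 0.005)
  expect_equal(s$rho_6mv, 0.919, tolerance = 0.005)
  expect_lt(s$p_all, 0.05)
  # bit-stable: a pure function of the packaged fixture
  expect_identical(s, reproduce_table3_stats())
  expect_error(reproduce_table3_stats(read_table3()[1:10, ]), "18")
})
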