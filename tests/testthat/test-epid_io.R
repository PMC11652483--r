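test_that("PGM round-trips 16-bit data in both dialects", {
  set.seed(7)
  for (ascii in c(FALSE, TRUE)) {
    m <- matrix(sample.int(65536, 40 * 30, replace = TRUE) - 1L, 40, 30)
    p <- withr::local_tempfile(fileext = ".pgm")
    write_pgm(m, p, ascii = ascii)
    expect_identical(read_pgm(p), m)
  }
})

test_that("8-bit PGM is accepted with a degraded-source warning", {
  p <- withr::local_tempfile(fileext = ".pgm")
  con <- file(p, "wb")
  writeChar("P5\n2 2\n255\n", con, eos = NULL)
  writeBin(as.raw(c(0, 128, 255, 1)), con)
  close(con)
  expect_warning(m <- read_pgm(p), "degraded")
  expect_identical(m, matrix(c(0L, 128L, 255L, 1L) * 257L, 2, 2, byrow = TRUE))
})

test_that("frame sequences read back ordered, timestamped and idempotent", {
  d <- withr::local_tempdir()
  px <- matrix(1000L, 32, 32)
  frames <- lapply(0:2, function(k) raw_frame(px + k, k, 0.3 * k))
  log <- acquisition_log(c(0, 0.3, 0.6), c(100, 100, 100))
  write_frame_sequence(frames, log, d)
  s1 <- read_frame_sequence(d)
  expect_length(s1$frames, 3)
  expect_equal(vapply(s1$frames, `[[`, 0, "timestamp"), c(0, 0.3, 0.6))
  expect_equal(vapply(s1$frames, `[[`, 0L, "frame_index"), 0:2)
  expect_identical(s1$frames[[2]]$pixels, px + 1L)
  s2 <- read_frame_sequence(d)
  expect_identical(s1, s2)
})

test_that("frame sequence errors name the problem", {
  d <- withr::local_tempdir()
  expect_error(read_frame_sequence(d), "missing acquisition log")
  writeLines(c("# EPIDACQ/1.0", "0 0.0 100", "1 0.3 100"),
             file.path(d, "acquisition.log"))
  expect_error(read_frame_sequence(d), "no frames found")
  write_pgm(matrix(5L, 8, 8), file.path(d, "frame_0000.pgm"))
  expect_error(read_frame_sequence(d), "frame count mismatch")
})

test_that("raw_frame validates the 16-bit contract", {
  expect_error(raw_frame(matrix(-1, 4, 4), 0, 0), "16-bit|\\[0, 65535\\]")
  expect_error(raw_frame(matrix(70000, 4, 4), 0, 0), "\\[0, 65535\\]")
  expect_error(raw_frame(matrix(1.5, 4, 4), 0, 0), "integer")
  expect_error(raw_frame(matrix(1L, 4, 5), 0, 0), "square")
})

test_that("RT plan files round-trip every control point field", {
  plan <- toy_plan()
  p <- withr::local_tempfile(fileext = ".json")
  write_rtplan(plan, p)
  back <- read_rtplan(p)
  expect_equal(back$total_mu, plan$total_mu, tolerance = 1e-9)
  expect_equal(length(back$control_points), 3)
  for (k in 1:3) {
    expect_equal(back$control_points[[k]]$bank_A,
                 plan$control_points[[k]]$bank_A, tolerance = 1e-6)
    expect_equal(back$control_points[[k]]$gantry_angle,
                 plan$control_points[[k]]$gantry_angle, tolerance = 1e-6)
  }
})

test_that("a dense generated arc reads back with full bookkeeping", {
  plan <- synthetic_arc_plan(n_cp = 180, total_mu = 333.5)
  p <- withr::local_tempfile(fileext = ".json")
  write_rtplan(plan, p)
  back <- read_rtplan(p)
  expect_length(back$control_points, 180)
  expect_equal(back$total_mu, 333.5, tolerance = 1e-9)
})

test_that("invalid plans are rejected", {
  cps <- list(plan_control_point(0L, 0, 0, 10, -5, 5),
              plan_control_point(1L, 10, 0, 5, -5, 5))
  expect_error(vmat_plan("bad", "6", cps, 10), "non-decreasing")
  expect_error(vmat_plan("static", "6", cps[1], 10), "at least 2")
  expect_error(plan_control_point(0L, 0, 0, 1, 5, -5), "bank_B")
})

test_that("the packaged 18-plan table matches its transcription checksums", {
  tab <- read_table3()
  expect_equal(nrow(tab), 18)
  bone <- tab[tab$site == "Bone", ]
  expect_equal(bone$gpr_prop, 95.2)
  expect_equal(bone$mu, 1639)
  expect_equal(sum(tab$beam == "6 FFF"), 6)
  expect_equal(sum(tab$gpr_prop), 1713.8)
})

test_that("table fixture parsing errors name row and column", {
  tab <- read_table3()
  tab$aav[4] <- NA
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, p, row.names = FALSE)
  expect_error(read_table3(p), "aav.*row 4")
  expect_error(read_table3(system.file("DESCRIPTION", package = "epidlog")),
               "columns|rows")
})
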