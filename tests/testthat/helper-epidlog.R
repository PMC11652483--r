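# shared fixtures, all built in code

# 3-control-point toy arc used for the hand-checked complexity values
toy_plan <- function() {
  cps <- list(
    plan_control_point(0L, 179, 0, 0,   c(-10, -11, -13), c(10, 12, 16)),
    plan_control_point(1L, 270, 0, 40,  c(-8, -9, -12),   c(12, 13, 15)),
    plan_control_point(2L, 1, 0, 100,   c(-5, -7, -8),    c(5, 6, 9)))
  vmat_plan("toy", "6", cps, rep(10, 3))
}

# static constant-aperture sweep (no modulation)
static_plan <- function(n_cp = 5) {
  cps <- lapply(seq_len(n_cp), function(k) {
    plan_control_point(k - 1L, (k - 1) * 10, 0, (k - 1) * 25,
                       rep(-20, 4), rep(20, 4))
  })
  vmat_plan("static", "6", cps, rep(10, 4))
}

# small fast arc acquisition for end-to-end tests
quick_acq <- function(n_frames = 6, blur_sigma = 2, noise_sd = 0, seed = 1L,
                      offsets = NULL) {
  plan <- synthetic_arc_plan(n_cp = 31, n_pairs = 12, sweep_mm = 20,
                             window_mm = 24, total_mu = 120)
  gen_vmat_acquisition(plan, n_frames = n_frames,
                       geometry = detector_geometry(256, 0.5),
                       blur_sigma = blur_sigma, noise_sd = noise_sd,
                       offsets = offsets, seed = seed)
}

quick_config <- function() {
  pipeline_config(detector = list(resolution = 256L, pixel_mm = 0.5))
}
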