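#' Dose-proportional fluence image
#'
#' @param values Non-negative numeric matrix.
#' @param stage One of `"processed"` (inverted raw), `"deconvolved"`, or
#'   `"ideal"` (synthetic ground truth).
#' @return An object of class `fluence_image`.
#' @export
fluence_image <- function(values, stage = c("processed", "deconvolved", "ideal")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("non-finite values in fluence image")
  if (min(values) < 0) stop("fluence values must be non-negative")
  structure(list(values = values, stage = stage), class = "fluence_image")
}

#' Invert a raw EPID frame to a dose-proportional image
#'
#' The panel calibration stores intensities inversely proportional to dose in
#' 16-bit range, so the processed image is `65535 - raw`, elementwise. The
#' operation is an involution on valid frames.
#'
#' @param frame A [raw_frame()] or a 16-bit matrix.
#' @return A [fluence_image()] with `stage = "processed"`.
#' @export
invert_raw <- function(frame) {
  px <- if (inherits(frame, "raw_frame")) frame$pixels else as.matrix(frame)
  if (min(px) < 0 || max(px) > 65535) stop("pixel values outside 16-bit range")
  fluence_image(65535 - px, stage = "processed")
}

#' Gaussian blur kernel
#'
#' Discrete sampled 2D Gaussian, truncated at `half_width` pixels and
#' renormalized to unit sum. The kernel is separable; the 1D factor is kept
#' alongside the 2D weights so convolution can run as two 1D passes.
#'
#' @param sigma Standard deviation in pixels, > 0.
#' @param half_width Truncation radius in pixels; `>= 3 * sigma` recommended
#'   (default `ceiling(4 * sigma)`).
#' @return An object of class `blur_kernel` with fields `sigma`, `half_width`,
#'   `g` (1D factor) and `weights` (2D, unit sum).
#' @export
gaussian_kernel <- function(sigma, half_width = ceiling(4 * sigma)) {
  if (sigma <= 0) stop("sigma must be > 0")
  half_width <- max(0L, as.integer(half_width))
  x <- seq(-half_width, half_width)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  structure(list(sigma = sigma, half_width = half_width, g = g,
                 weights = outer(g, g)),
            class = "blur_kernel")
}

#' Delta (identity) kernel
#'
#' @return A `blur_kernel` whose convolution is the identity.
#' @export
delta_kernel <- function() {
  structure(list(sigma = 0, half_width = 0L, g = 1, weights = matrix(1, 1, 1)),
            class = "blur_kernel")
}

# Banded 1D convolution operator with reflective (symmetric, whole-sample)
# boundary handling, as a dense n x n matrix. Applied as A %*% X (rows) and
# X %*% t(A) (columns). Dense matrix-multiply beats FFT here because the
# operator is reused across frames and BLAS does the work.
conv_operator <- function(n, g) {
  hw <- (length(g) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - hw):(i + hw)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    for (k in seq_along(idx)) A[i, idx[k]] <- A[i, idx[k]] + g[k]
  }
  A
}

# cache of conv operators keyed by size/kernel, private to the package
.conv_cache <- new.env(parent = emptyenv())

#' Convolve an image with a blur kernel (reflective boundaries)
#'
#' @param values Numeric matrix.
#' @param kernel A [gaussian_kernel()] or [delta_kernel()].
#' @return Matrix of the same shape.
#' @export
convolve_image <- function(values, kernel) {
  values <- as.matrix(values)
  if (2L * kernel$half_width + 1L > min(dim(values))) {
    stop("kernel larger than image")
  }
  if (kernel$half_width == 0L) return(values)
  key <- sprintf("n%d_hw%d_s%.8g", nrow(values), kernel$half_width, kernel$sigma)
  A <- .conv_cache[[key]]
  if (is.null(A) || nrow(A) != nrow(values)) {
    A <- conv_operator(nrow(values), kernel$g)
    .conv_cache[[key]] <- A
  }
  if (nrow(values) == ncol(values)) {
    A %*% values %*% t(A)
  } else {
    keyc <- sprintf("n%d_hw%d_s%.8g", ncol(values), kernel$half_width, kernel$sigma)
    Ac <- .conv_cache[[keyc]]
    if (is.null(Ac)) {
      Ac <- conv_operator(ncol(values), kernel$g)
      .conv_cache[[keyc]] <- Ac
    }
    A %*% values %*% t(Ac)
  }
}

#' Additive iterative deconvolution
#'
#' Removes scatter blur from a processed EPID image. With `b` the processed
#' image and `K` the kernel, the scheme iterates
#' \deqn{x_{n+1} = x_n + b - x_n * K}
#' starting from `x_1 = b` (a van Cittert-type additive update). The residual
#' `r_n = ||x_n * K - b||_2` is monitored and iteration stops when its
#' relative change `|r_n - r_{n-1}| / r_1` falls below `tol` ("saturates") or
#' at `max_iter`. Intermediate negative values are permitted (the additive
#' update can undershoot); the returned image is clipped to be non-negative.
#'
#' @param image A [fluence_image()] with `stage = "processed"`.
#' @param kernel A [gaussian_kernel()].
#' @param tol Relative residual-change stopping threshold.
#' @param max_iter Iteration cap.
#' @return An object of class `deconvolution_result`: `image` (stage
#'   `"deconvolved"`), `n_iterations`, `residual_history`.
#' @export
iterative_deconvolve <- function(image, kernel, tol = 1e-4, max_iter = 50L) {
  stopifnot(inherits(image, "fluence_image"))
  if (image$stage != "processed") {
    stop("deconvolution expects a 'processed' stage image")
  }
  if (tol <= 0) stop("tol must be > 0")
  b <- image$values
  if (!all(is.finite(b))) stop("non-finite values in input image")
  x <- b
  residuals <- numeric(0)
  n <- 0L
  repeat {
    n <- n + 1L
    blurred <- convolve_image(x, kernel)
    r <- sqrt(sum((blurred - b)^2))
    residuals <- c(residuals, r)
    if (n >= max_iter) break
    if (n >= 2 && abs(residuals[n] - residuals[n - 1]) / max(residuals[1], .Machine$double.eps) < tol) break
    if (r == 0) break
    x <- x + b - blurred
  }
  out <- pmax(x, 0)
  structure(list(image = fluence_image(out, stage = "deconvolved"),
                 n_iterations = n, residual_history = residuals),
            class = "deconvolution_result")
}
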