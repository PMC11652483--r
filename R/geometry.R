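#' Detector geometry
#'
#' Describes the EPID panel as seen at the isocenter plane. The detector is a
#' square grid of `resolution` x `resolution` pixels; `pixel_mm` is the pixel
#' pitch projected to the isocenter plane, so a 5 cm field spans
#' `50 / pixel_mm` pixels. Pixel columns use half-open spans: column `j`
#' (0-based) covers the boundary interval `[j, j + 1)`, and the beam axis sits
#' at boundary coordinate `resolution / 2` in both axes (between the two
#' central pixels). Rows run top to bottom (in-plane, leaf-stacking axis);
#' columns run left to right (cross-plane, leaf-travel axis).
#'
#' @param resolution Side length of the square detector in pixels.
#' @param pixel_mm Pixel pitch at the isocenter plane, in mm.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(resolution = 512L, pixel_mm = 0.5) {
  resolution <- as.integer(resolution)
  stopifnot(resolution >= 16L, pixel_mm > 0)
  structure(list(resolution = resolution, pixel_mm = pixel_mm),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d x %d px, %.3g mm/px at isocenter\n",
              x$resolution, x$resolution, x$pixel_mm))
  invisible(x)
}

# mm position (signed about beam axis) of a pixel *boundary* coordinate
boundary_to_mm <- function(boundary, geometry) {
  (boundary - geometry$resolution / 2) * geometry$pixel_mm
}

mm_to_boundary <- function(mm, geometry) {
  geometry$resolution / 2 + mm / geometry$pixel_mm
}

#' Leaf-pair row bands on the detector
#'
#' Projects the leaf stack onto detector rows. Leaves are stacked centered on
#' the beam axis; pair `i` occupies a contiguous band of rows whose height is
#' `leaf_widths[i] / pixel_mm` pixels. Widths must project to whole pixel
#' counts (the panel cannot resolve fractional leaf boundaries and the
#' extraction works in integer row bands).
#'
#' @param leaf_widths Numeric vector of leaf widths in mm, one per pair.
#' @param geometry A [detector_geometry()].
#' @return Integer matrix with one row per pair and columns `first`, `last`
#'   (1-based inclusive detector row indices).
#' @export
leaf_row_bands <- function(leaf_widths, geometry) {
  px <- leaf_widths / geometry$pixel_mm
  if (any(abs(px - round(px)) > 1e-9)) {
    stop("leaf widths must project to whole pixel counts at this geometry")
  }
  px <- as.integer(round(px))
  total <- sum(px)
  if (total > geometry$resolution) stop("leaf stack exceeds detector height")
  top <- as.integer(round(geometry$resolution / 2 - total / 2))
  last <- top + cumsum(px)
  first <- c(top, last[-length(last)]) + 1L
  cbind(first = first, last = as.integer(last))
}
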