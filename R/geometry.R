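#' Stack geometry: the physical calibration of a serial-section stack
#'
#' Bundles the three lengths that convert pixel measurements into physical
#' units: the cut thickness of each section, the spacing discarded between
#' consecutive sections, and the in-plane size of one pixel. At the default
#' sectioning protocol (20 µm sections every 500 µm) one section accounts
#' for an axial increment of `0.52` mm.
#'
#' @param section_thickness_mm Thickness of each physical section, mm.
#' @param section_spacing_mm Gap between consecutive sections, mm.
#' @param pixel_size_mm Side length of one image pixel, mm. The default is a
#'   placeholder calibration for low-magnification bright-field images and
#'   should be replaced by the true microscope calibration when known.
#' @return An object of class `stack_geometry`.
#' @examples
#' g <- stack_geometry()
#' slice_increment(g)  # 0.52 mm
#' @export
stack_geometry <- function(section_thickness_mm = 0.02,
                           section_spacing_mm = 0.5,
                           pixel_size_mm = 0.004) {
  vals <- c(section_thickness_mm, section_spacing_mm, pixel_size_mm)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all stack_geometry fields must be strictly positive finite numbers",
         call. = FALSE)
  }
  structure(
    list(section_thickness_mm = section_thickness_mm,
         section_spacing_mm = section_spacing_mm,
         pixel_size_mm = pixel_size_mm),
    class = "stack_geometry"
  )
}

#' Axial increment accounted for by one section
#'
#' @param geometry A [stack_geometry()].
#' @return Thickness + spacing, in mm (0.52 at defaults).
#' @export
slice_increment <- function(geometry) {
  stopifnot(inherits(geometry, "stack_geometry"))
  geometry$section_thickness_mm + geometry$section_spacing_mm
}

#' Area of one pixel in mm^2
#' @param geometry A [stack_geometry()].
#' @export
pixel_area_mm2 <- function(geometry) {
  stopifnot(inherits(geometry, "stack_geometry"))
  geometry$pixel_size_mm^2
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat("stack_geometry: thickness", x$section_thickness_mm,
      "mm, spacing", x$section_spacing_mm,
      "mm (increment", slice_increment(x), "mm), pixel",
      x$pixel_size_mm, "mm\n")
  invisible(x)
}

#' Convert mm^2 to a pixel count under a calibration
#' @param area_mm2 Area in mm^2.
#' @param geometry A [stack_geometry()].
#' @return Number of pixels (not rounded).
#' @keywords internal
mm2_to_px <- function(area_mm2, geometry) area_mm2 / pixel_area_mm2(geometry)
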