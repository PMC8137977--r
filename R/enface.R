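#' En face OCTA image
#'
#' Container for a 2D grayscale en face angiogram with a physical pixel scale.
#' Intensities are min-max normalized to `[0, 1]` on construction; a constant
#' image maps to all zeros so that downstream filter parameters always live on
#' a fixed intensity scale.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = y, columns
#'   = x).
#' @param pixel_scale_mm Physical size of one pixel in mm (isotropic). Defaults
#'   to `3/304` mm, the pitch of a 3 x 3 mm scan sampled on a 304 x 304 grid.
#' @param normalize Min-max normalize to `[0, 1]`? Set `FALSE` only when the
#'   input is already on that scale (used internally by filters that must not
#'   re-stretch their output).
#' @param source Optional provenance string (file path).
#'
#' @return An object of class `enface_image` with fields `pixels`,
#'   `height_px`, `width_px`, `pixel_scale_mm`, `source`.
#' @export
enface_image <- function(pixels, pixel_scale_mm = DEFAULT_PIXEL_SCALE_MM,
                         normalize = TRUE, source = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_validation("`pixels` must be a numeric matrix")
  if (nrow(pixels) == 0L || ncol(pixels) == 0L)
    stop_validation("zero-sized image")
  if (!all(is.finite(pixels)))
    stop_validation("image contains non-finite intensities")
  if (!is_scalar_number(pixel_scale_mm) || pixel_scale_mm <= 0)
    stop_validation("`pixel_scale_mm` must be a positive number")
  if (normalize) {
    rng <- range(pixels)
    pixels <- if (rng[2] > rng[1]) (pixels - rng[1]) / (rng[2] - rng[1])
              else array(0, dim = dim(pixels))
  } else if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9) {
    stop_validation("un-normalized pixels must already lie in [0, 1]")
  }
  structure(
    list(pixels = pixels, height_px = nrow(pixels), width_px = ncol(pixels),
         pixel_scale_mm = pixel_scale_mm, source = source),
    class = "enface_image"
  )
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, %.4f mm/px (%.2f x %.2f mm)\n",
              x$height_px, x$width_px, x$pixel_scale_mm,
              x$height_px * x$pixel_scale_mm, x$width_px * x$pixel_scale_mm))
  invisible(x)
}

# Collapse an RGB(A) array to luminance (Rec. 709 weights); pass grayscale
# matrices through.
collapse_luminance <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    if (nc == 1L) return(a[, , 1])
    # ignore alpha if present
    return(0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3])
  }
  stop_io("unsupported raster layout")
}

#' Load an en face angiogram from PNG or TIFF
#'
#' Reads an 8- or 16-bit grayscale or RGB raster, collapses RGB to luminance,
#' and min-max normalizes intensities to `[0, 1]`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams enface_image
#' @return An [enface_image].
#' @export
load_enface_image <- function(path, pixel_scale_mm = DEFAULT_PIXEL_SCALE_MM) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_io(sprintf("cannot read image file '%s'", paste(path, collapse = ",")))
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e) stop_io(conditionMessage(e))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path), error = function(e) stop_io(conditionMessage(e))),
    stop_io(sprintf("unsupported raster format '.%s' (PNG/TIFF only)", ext))
  )
  px <- collapse_luminance(a)
  if (length(px) == 0L) stop_validation("zero-sized image")
  enface_image(px, pixel_scale_mm = pixel_scale_mm, source = path)
}

#' Save an en face image (or any `[0,1]` matrix) as 8-bit grayscale PNG
#'
#' Round-tripping through [load_enface_image()] recovers intensities up to
#' 8-bit quantization.
#'
#' @param img An [enface_image] or numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_enface_png <- function(img, path) {
  px <- if (inherits(img, "enface_image")) img$pixels else img
  png::writePNG(pmin(pmax(px, 0), 1), target = path)
  invisible(path)
}
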