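# Even-odd (crossing number) point-in-polygon test, vectorized over points.
# Polygon vertices (vx, vy) in corner-based pixel coordinates; points on an
# edge follow the half-open crossing rule of the ray cast.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_signed_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  sum(vx[j] * vy - vx * vy[j]) / 2
}

#' Lesion mask from a manually drawn contour
#'
#' Rasterizes a polygonal mCNV contour into a boolean mask congruent with its
#' en face image. Coordinates are corner-based and 0-based: pixel `(row r,
#' col c)` covers the unit square `[c, c+1] x [r, r+1]` and its center sits at
#' `(c + 0.5, r + 0.5)`. A pixel is foreground iff its center is inside the
#' polygon under the even-odd rule.
#'
#' @param vertices Two-column matrix or data.frame of polygon vertices with
#'   columns `x` (column direction) and `y` (row direction), in pixel units.
#'   At least 3 non-collinear vertices; vertices outside the image are clipped
#'   to its bounds.
#' @param shape Integer `(height, width)` of the target image.
#' @param pixel_scale_mm Physical pixel pitch carried along for area
#'   conversions.
#' @return An object of class `lesion_mask`: list with `mask` (logical
#'   matrix), `source_contour` (the clipped vertex matrix) and
#'   `pixel_scale_mm`.
#' @export
rasterize_contour <- function(vertices, shape,
                              pixel_scale_mm = DEFAULT_PIXEL_SCALE_MM) {
  v <- as.matrix(as.data.frame(vertices))
  if (is.data.frame(vertices) && all(c("x", "y") %in% colnames(v)))
    v <- v[, c("x", "y"), drop = FALSE]
  if (ncol(v) < 2L) stop_validation("`vertices` needs x and y columns")
  v <- v[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  # drop a duplicated closing vertex
  if (nrow(v) > 1L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stop_validation("a contour needs at least 3 vertices")
  if (!all(is.finite(v))) stop_validation("contour vertices must be finite")
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (is.na(h) || is.na(w) || h < 1L || w < 1L) stop_validation("bad mask shape")
  v[, 1] <- pmin(pmax(v[, 1], 0), w)
  v[, 2] <- pmin(pmax(v[, 2], 0), h)
  if (abs(polygon_signed_area(v[, 1], v[, 2])) < .Machine$double.eps)
    stop_validation("degenerate contour: vertices are collinear")
  mask <- matrix(FALSE, h, w)
  rows <- max(1L, floor(min(v[, 2])) ) : min(h, ceiling(max(v[, 2])))
  cols <- max(1L, floor(min(v[, 1])) ) : min(w, ceiling(max(v[, 1])))
  cx <- rep(cols - 0.5, each = length(rows))   # pixel centers, corner-based
  cy <- rep(rows - 0.5, times = length(cols))
  inside <- point_in_polygon(cx, cy, v[, 1], v[, 2])
  mask[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <- inside
  lesion_mask(mask, source_contour = v, pixel_scale_mm = pixel_scale_mm)
}

#' Construct a lesion mask from a logical matrix
#'
#' @param mask Logical matrix (TRUE = inside the lesion).
#' @param source_contour Optional vertex matrix the mask was rasterized from.
#' @param pixel_scale_mm Physical pixel pitch.
#' @return A `lesion_mask` object.
#' @export
lesion_mask <- function(mask, source_contour = NULL,
                        pixel_scale_mm = DEFAULT_PIXEL_SCALE_MM) {
  if (!is.matrix(mask)) stop_validation("`mask` must be a matrix")
  mask <- mask != 0
  structure(list(mask = mask, source_contour = source_contour,
                 pixel_scale_mm = pixel_scale_mm),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d px, %d foreground px (%.4f mm^2)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              sum(x$mask) * x$pixel_scale_mm^2))
  invisible(x)
}

#' Read a lesion contour from CSV or JSON
#'
#' CSV files must have columns `x` and `y` (pixel units, corner-based).
#' JSON files may be either an object with `x`/`y` arrays or a GeoJSON-style
#' nested coordinate array `[[x1, y1], [x2, y2], ...]` (one ring).
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return A two-column numeric matrix with columns `x`, `y`.
#' @export
read_contour <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read contour file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- read.csv(path)
    if (!all(c("x", "y") %in% names(d)))
      stop_validation("contour CSV needs columns x and y")
    return(cbind(x = d$x, y = d$y))
  }
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(j) && !is.null(j$coordinates)) j <- j$coordinates
    if (is.list(j) && !is.null(j$x) && !is.null(j$y))
      return(cbind(x = as.numeric(j$x), y = as.numeric(j$y)))
    if (is.array(j) && length(dim(j)) == 3L) j <- j[1, , ]  # single-ring GeoJSON
    j <- as.matrix(j)
    if (ncol(j) != 2L) stop_validation("JSON contour must be an n x 2 ring")
    return(cbind(x = j[, 1], y = j[, 2]))
  }
  stop_io(sprintf("unsupported contour format '.%s'", ext))
}

#' Write a boolean mask as a 0/255 PNG
#'
#' @param mask A `lesion_mask` or logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "lesion_mask")) mask$mask else mask
  png::writePNG(m * 1, target = path)
  invisible(path)
}

#' Read a 0/255 PNG back into a lesion mask
#'
#' @param path PNG path.
#' @inheritParams lesion_mask
#' @return A `lesion_mask`.
#' @export
read_mask_png <- function(path, pixel_scale_mm = DEFAULT_PIXEL_SCALE_MM) {
  if (!file.exists(path)) stop_io(sprintf("cannot read mask file '%s'", path))
  a <- collapse_luminance(png::readPNG(path))
  lesion_mask(a > 0.5, pixel_scale_mm = pixel_scale_mm)
}
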