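#' Physical area of a mask
#'
#' Foreground pixel count times the squared pixel pitch.
#'
#' @param mask Logical matrix, [lesion_mask], or `binary_vessel_map`.
#' @param pixel_scale_mm Pixel pitch in mm (taken from the object when given).
#' @return Area in mm^2.
#' @export
area_mm2 <- function(mask, pixel_scale_mm = NULL) {
  if (inherits(mask, "lesion_mask")) {
    pixel_scale_mm <- pixel_scale_mm %||% mask$pixel_scale_mm
    mask <- mask$mask
  } else if (inherits(mask, "binary_vessel_map")) {
    pixel_scale_mm <- pixel_scale_mm %||% mask$pixel_scale_mm
    mask <- mask$mask
  }
  pixel_scale_mm <- pixel_scale_mm %||% DEFAULT_PIXEL_SCALE_MM
  sum(mask != 0) * pixel_scale_mm^2
}

#' Vessel density inside the lesion
#'
#' Fraction of lesion pixels occupied by binarized vessels.
#'
#' @param binary A `binary_vessel_map`.
#' @return Fraction in `[0, 1]`.
#' @export
vessel_density <- function(binary) {
  if (!inherits(binary, "binary_vessel_map"))
    stop_validation("`binary` must be a binary_vessel_map")
  n_lesion <- sum(binary$lesion$mask)
  if (n_lesion == 0L) stop_validation("empty lesion mask")
  sum(binary$mask) / n_lesion
}

#' Mean vessel caliber
#'
#' Non-skeletonized vessel area divided by skeletonized total vessel length,
#' expressed in micrometers (mm^2 / mm = mm, x 1000).
#'
#' @param vessel_area_mm2 Vessel area (mm^2).
#' @param vessel_length_mm Skeleton length (mm), must be positive.
#' @return Mean caliber in um.
#' @export
vessel_diameter_um <- function(vessel_area_mm2, vessel_length_mm) {
  if (!is_scalar_number(vessel_length_mm) || vessel_length_mm <= 0)
    stop_undefined("vessel diameter is undefined for zero vessel length")
  1000 * vessel_area_mm2 / vessel_length_mm
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes over dyadic box sizes `s in {2, 4, 8, ...,
#' min(h, w)/4}`, boxes anchored at the origin of the foreground bounding
#' box, and returns the least-squares slope of `log N(s)` against
#' `log(1/s)`. Higher values indicate a more complex branching pattern.
#'
#' @param skel A `skeleton_map`, logical matrix, or any binary point set.
#' @param offsets Number of diagonal grid offsets per box size. The default 1
#'   anchors the grid at the bounding-box origin (fully deterministic,
#'   testable against analytic sets); larger values average the box count
#'   over shifted grids, which lowers the variance of the estimate on small
#'   point sets.
#' @return The fitted dimension (about 1 for a line, 2 for a filled plane).
#' @export
fractal_dimension <- function(skel, offsets = 1) {
  m <- if (inherits(skel, "skeleton_map")) skel$mask else skel != 0
  if (!any(m)) stop_undefined("fractal dimension is undefined for an empty set")
  smax <- min(dim(m)) / 4
  sizes <- 2^(1:30)
  sizes <- sizes[sizes <= smax]
  if (length(sizes) < 3L)
    stop_validation("image too small for box counting (need >= 3 dyadic sizes)")
  idx <- which(m, arr.ind = TRUE)
  r0 <- idx[, 1] - min(idx[, 1])      # anchor at bounding-box origin
  c0 <- idx[, 2] - min(idx[, 2])
  n_boxes <- vapply(sizes, function(s) {
    offs <- unique(floor(seq(0, s - 1, length.out = max(1, offsets))))
    mean(vapply(offs, function(o)
      length(unique(((r0 + o) %/% s) * 2^31 + (c0 + o) %/% s)), numeric(1)))
  }, numeric(1))
  unname(coef(lm(log(n_boxes) ~ log(1 / sizes)))[2])
}

# Arc length of a branch path measured on a stride-resampled chord chain.
# The raw (1, sqrt2) chain step-sum overestimates smooth arcs by ~5% on
# average over directions; summing chords between every `stride`-th path pixel
# (endpoints always kept) removes that digitization bias while leaving
# straight and axis-aligned paths exact. stride = 1 reproduces the raw
# step-sum.
resampled_arc_px <- function(xy, stride = 5) {
  n <- nrow(xy)
  if (n < 2L) return(0)
  if (stride <= 1L) return(step_sum_px(xy))
  keep <- unique(c(seq(1L, n, by = as.integer(stride)), n))
  p <- xy[keep, , drop = FALSE]
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Mean branch tortuosity
#'
#' Per branch, the actual centerline length divided by the straight (chord)
#' length between its two ends; 1 = perfectly straight. For cycles (and loops
#' anchored at a single node) the chord is the maximum pairwise distance
#' within the path (the loop diameter). The aggregate is the unweighted mean
#' over branches by default.
#'
#' @param graph A [build_graph()] result.
#' @param smooth_stride_px Stride (px) of the chord resampling used for branch
#'   arc length; 1 = raw chain step-sum (see `resampled_arc_px` note in the
#'   vignette).
#' @param weight `"unweighted"` (default) or `"length"` (weights branches by
#'   path length).
#' @param include_cycles Include cycle branches under the loop-diameter chord
#'   convention? Set `FALSE` to restrict to open branches.
#' @return Mean tortuosity `>= 1`.
#' @export
vessel_tortuosity <- function(graph, smooth_stride_px = 5,
                              weight = c("unweighted", "length"),
                              include_cycles = TRUE) {
  weight <- match.arg(weight)
  if (!inherits(graph, "skeleton_graph")) stop_validation("`graph` must be a skeleton_graph")
  br <- graph$branches
  use <- br$chord_px > 0 & (include_cycles | !br$is_cycle)
  if (!any(use)) stop_undefined("tortuosity is undefined without non-degenerate branches")
  arc <- vapply(which(use), function(i) {
    xy <- graph$paths[[i]]
    if (br$is_cycle[i]) xy <- rbind(xy, xy[1, ])   # include the closing step
    resampled_arc_px(xy, smooth_stride_px)
  }, numeric(1))
  tort <- pmax(arc / br$chord_px[use], 1)
  if (weight == "unweighted") mean(tort)
  else sum(tort * br$path_length_px[use]) / sum(br$path_length_px[use])
}

#' Compute the full nine-biomarker panel for one lesion
#'
#' Runs the complete chain binarize -> skeletonize -> graph -> metrics and
#' returns the panel of OCTA biomarkers: mCNV area, vessel area, vessel
#' density, vessel length, mean vessel diameter, box-counting fractal
#' dimension, junction count, junction density, and branch tortuosity, plus
#' the externally supplied central retinal thickness (CRT).
#'
#' A lesion with no detected vessels gives zeroed vessel metrics and `NA` for
#' the markers that are genuinely undefined there (diameter, fractal
#' dimension, tortuosity, junction density); they are reported as missing,
#' never as 0.
#'
#' @param img An [enface_image].
#' @param lesion A congruent [lesion_mask].
#' @param params A [vessel_params] record.
#' @param crt_um Optional central retinal thickness in um (from structural
#'   OCT; carried through unchanged).
#' @param keep_intermediates Attach the binary map, skeleton and graph as
#'   attribute `"intermediates"`?
#' @return An object of class `biomarker_panel` (a named list; see
#'   [as.data.frame.biomarker_panel()] for the tabular form).
#' @export
compute_panel <- function(img, lesion, params = vessel_params(), crt_um = NULL,
                          keep_intermediates = FALSE) {
  binary <- binarize_lesion(img, lesion, params)
  skel <- skeletonize(binary)
  graph <- build_graph(skel, prune_px = params$prune_px,
                       merge_junction_px = params$merge_junction_px)
  scale <- img$pixel_scale_mm
  mcnv_area <- area_mm2(lesion, scale)
  va <- area_mm2(binary, scale)
  vl <- total_length_mm(graph$mask, pixel_scale_mm = scale)
  vj <- junction_count(graph)
  has_vessels <- va > 0 && vl > 0
  panel <- list(
    mcnv_area_mm2 = mcnv_area,
    vessel_area_mm2 = va,
    vessel_density = if (mcnv_area > 0) va / mcnv_area else NA_real_,
    vessel_length_mm = vl,
    vessel_diameter_um = if (has_vessels) vessel_diameter_um(va, vl) else NA_real_,
    fractal_dimension = if (any(graph$mask)) tryCatch(fractal_dimension(graph$mask),
      octamorph_error = function(e) NA_real_) else NA_real_,
    vessel_junctions = vj,
    junction_density_per_mm = if (vl > 0) vj / vl else NA_real_,
    vessel_tortuosity = tryCatch(
      vessel_tortuosity(graph, smooth_stride_px = params$smooth_stride_px),
      octamorph_error = function(e) NA_real_),
    crt_um = crt_um %||% NA_real_
  )
  attr(panel, "params_hash") <- params_hash(params)
  attr(panel, "undefined") <- names(panel)[vapply(panel, function(x) is.na(x[1]), logical(1))]
  if (keep_intermediates)
    attr(panel, "intermediates") <- list(binary = binary, skeleton = skel, graph = graph)
  class(panel) <- "biomarker_panel"
  panel
}

#' @export
print.biomarker_panel <- function(x, ...) {
  df <- as.data.frame(x)
  cat("<biomarker_panel>\n")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tabular form of a biomarker panel
#'
#' One row with the conventional column names used in mCNV OCTA reports:
#' `mCNV_area` (mm^2), `VA` (vessel area, mm^2), `VLD` (vessel density), `FD`
#' (fractal dimension), `VD` (vessel diameter, um), `VL` (vessel length, mm),
#' `VT` (tortuosity), `VJ` (junctions), `JD` (junction density, n/mm), `CRT`
#' (um).
#'
#' @param x A `biomarker_panel`.
#' @param ... Unused.
#' @return A one-row data.frame.
#' @export
as.data.frame.biomarker_panel <- function(x, ...) {
  data.frame(mCNV_area = x$mcnv_area_mm2, VA = x$vessel_area_mm2,
             VLD = x$vessel_density, FD = x$fractal_dimension,
             VD = x$vessel_diameter_um, VL = x$vessel_length_mm,
             VT = x$vessel_tortuosity, VJ = x$vessel_junctions,
             JD = x$junction_density_per_mm, CRT = x$crt_um)
}
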