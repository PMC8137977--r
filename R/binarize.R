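#' Gaussian denoising of an en face angiogram
#'
#' Convolution with a normalized Gaussian kernel, reflective boundary
#' handling. `sigma_px = 0` is the identity; total intensity is conserved up
#' to boundary effects and a constant image is returned unchanged.
#'
#' @param img An [enface_image] (or numeric matrix in `[0, 1]`).
#' @param sigma_px Gaussian standard deviation in pixels, `>= 0`.
#' @return An [enface_image] with smoothed (not re-normalized) intensities.
#' @export
gaussian_denoise <- function(img, sigma_px = 1) {
  if (!is_scalar_number(sigma_px) || sigma_px < 0)
    stop_validation("`sigma_px` must be a non-negative number")
  m <- if (inherits(img, "enface_image")) img$pixels else img
  scale <- if (inherits(img, "enface_image")) img$pixel_scale_mm else DEFAULT_PIXEL_SCALE_MM
  if (sigma_px > 0) {
    k <- gaussian_kernel(sigma_px, 0L)
    m <- sep_conv(m, k, k)
    m <- pmin(pmax(m, 0), 1)  # clamp away convolution round-off
  }
  enface_image(m, pixel_scale_mm = scale, normalize = FALSE,
               source = if (inherits(img, "enface_image")) img$source else NULL)
}

#' Multiscale Frangi vesselness filter (bright ridges, 2D)
#'
#' Hessian-based tubularity score. At each scale `s` the image Hessian is
#' computed with gamma-normalized Gaussian derivative filters (`s^2`
#' multiplier), eigenvalues are ordered `|l1| <= |l2|`, and the vesselness
#'
#'   `V = exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`
#'
#' with blobness `Rb = l1/l2` and structureness `S = sqrt(l1^2 + l2^2)` is
#' kept where `l2 < 0` (bright ridge polarity, as for OCTA flow signal) and
#' zero elsewhere. The response is the per-pixel maximum over scales,
#' normalized to `[0, 1]` by its global maximum (an all-zero map stays zero).
#'
#' @param img [enface_image] or matrix in `[0, 1]` (typically the denoised
#'   angiogram).
#' @param scales_px Positive Gaussian scales in pixels; one per expected
#'   vessel half-width.
#' @param beta Blobness sensitivity (dimensionless), classic default 0.5.
#' @param c Structureness sensitivity. `NULL` (default) sets `c` per scale to
#'   half the 95th percentile of the nonzero structureness values, which keeps
#'   the parameter on the data's own second-derivative scale.
#' @param normalize Normalize the final map by its global maximum? Disable to
#'   inspect raw cross-scale maxima.
#' @return An object of class `vesselness_map`: list with `response` (matrix
#'   in `[0, 1]`), `scales_px`, `beta`, `c_used` (per scale).
#' @export
frangi_vesselness <- function(img, scales_px = c(1, 2, 3, 4), beta = 0.5,
                              c = NULL, normalize = TRUE) {
  if (length(scales_px) < 1L) stop_validation("need at least one scale")
  if (any(!is.finite(scales_px)) || any(scales_px <= 0))
    stop_validation("scales must be positive")
  if (!is_scalar_number(beta) || beta <= 0) stop_validation("beta must be > 0")
  m <- if (inherits(img, "enface_image")) img$pixels else img
  resp <- matrix(0, nrow(m), ncol(m))
  c_used <- numeric(length(scales_px))
  for (si in seq_along(scales_px)) {
    s <- scales_px[si]
    g0 <- gaussian_kernel(s, 0L)
    g1 <- gaussian_kernel(s, 1L)
    g2 <- gaussian_kernel(s, 2L)
    # rows = y, cols = x; gamma-normalization with exponent 1 => s^2 factor
    hxx <- s^2 * sep_conv(m, g0, g2)
    hyy <- s^2 * sep_conv(m, g2, g0)
    hxy <- s^2 * sep_conv(m, g1, g1)
    half_tr <- (hxx + hyy) / 2
    root <- sqrt(pmax(((hxx - hyy) / 2)^2 + hxy^2, 0))
    la <- half_tr + root
    lb <- half_tr - root
    big_a <- abs(la) >= abs(lb)
    l2 <- ifelse(big_a, la, lb)   # larger magnitude
    l1 <- ifelse(big_a, lb, la)
    s2 <- l1^2 + l2^2
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    cc <- if (is.null(c)) {
      nz <- s2[s2 > 0]
      if (length(nz)) 0.5 * sqrt(quantile(nz, 0.95, names = FALSE)) else 1
    } else c
    c_used[si] <- cc
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    # bright-ridge polarity; the small floor keeps convolution round-off on
    # structure-free images from masquerading as ridges
    v[l2 >= -1e-8] <- 0
    resp <- pmax(resp, v)
  }
  if (normalize && max(resp) > 0) resp <- resp / max(resp)
  structure(list(response = resp, scales_px = scales_px, beta = beta,
                 c_used = c_used),
            class = "vesselness_map")
}

#' Local adaptive thresholding
#'
#' A pixel is foreground iff its value exceeds the mean over a square window
#' centered on it plus `offset`. Local means use reflective boundary handling,
#' matching every other filter in the chain.
#'
#' @param vmap A `vesselness_map`, [enface_image] or numeric matrix.
#' @param window_px Odd window side length, `>= 3`.
#' @param offset Additive offset on the local mean.
#' @return Logical matrix of foreground pixels.
#' @export
local_adaptive_threshold <- function(vmap, window_px = 31, offset = 0) {
  if (!is_scalar_number(window_px) || window_px < 3 || window_px %% 2 == 0)
    stop_validation("`window_px` must be an odd integer >= 3")
  m <- if (inherits(vmap, "vesselness_map")) vmap$response
       else if (inherits(vmap, "enface_image")) vmap$pixels
       else vmap
  m > local_mean(m, as.integer(window_px)) + offset
}

#' Binarization parameter record
#'
#' One flat record of every tunable in the binarize / skeletonize chain,
#' serializable to JSON (and YAML) so each run can log the exact parameters it
#' resolved.
#'
#' @param sigma_px Gaussian denoising sigma (px).
#' @param scales_px Frangi scales (px).
#' @param beta Frangi blobness sensitivity.
#' @param c Frangi structureness sensitivity; `NULL` = data-adaptive (half the
#'   95th percentile of structureness per scale).
#' @param window_px Adaptive-threshold window side (odd px).
#' @param offset Adaptive-threshold offset.
#' @param min_object_px Remove 8-connected foreground components smaller than
#'   this many pixels (0 disables).
#' @param threshold_on `"combined"` (default) thresholds the denoised
#'   intensity and keeps only pixels whose Frangi response clears
#'   `vessel_gate` — the combined strategy preserves vessel caliber (the
#'   adaptive threshold) while the vesselness term suppresses non-tubular
#'   clutter. `"vesselness"` thresholds the Frangi response itself;
#'   `"intensity"` uses the denoised image alone.
#' @param vessel_gate Fraction of the maximum vesselness below which pixels
#'   are discarded in `"combined"` mode.
#' @param prune_px Skeleton spur-pruning length (px); endpoint branches not
#'   longer than this are removed before metrics.
#' @param merge_junction_px Junction-bridge contraction length for
#'   [build_graph()].
#' @param smooth_stride_px Chord-resampling stride (px) for branch arc length
#'   in the tortuosity biomarker; 1 = raw chain step-sum.
#' @return A `vessel_params` list.
#' @export
vessel_params <- function(sigma_px = 0.8, scales_px = c(1, 2, 3, 4), beta = 0.5,
                          c = NULL, window_px = 31, offset = 0.15,
                          min_object_px = 10,
                          threshold_on = c("combined", "vesselness", "intensity"),
                          vessel_gate = 0.01,
                          prune_px = 3, merge_junction_px = 8,
                          smooth_stride_px = 5) {
  threshold_on <- match.arg(threshold_on)
  p <- list(sigma_px = sigma_px, scales_px = scales_px, beta = beta, c = c,
            window_px = window_px, offset = offset,
            min_object_px = min_object_px, threshold_on = threshold_on,
            vessel_gate = vessel_gate, prune_px = prune_px,
            merge_junction_px = merge_junction_px,
            smooth_stride_px = smooth_stride_px)
  class(p) <- "vessel_params"
  p
}

#' Write / read a parameter record (JSON or YAML)
#'
#' @param params A [vessel_params] record.
#' @param path Destination ending in `.json` or `.yaml`/`.yml`.
#' @return `path` invisibly (`write_params`); a [vessel_params]
#'   (`read_params`).
#' @export
write_params <- function(params, path) {
  ext <- tolower(tools::file_ext(path))
  p <- unclass(params)
  if (ext == "json") {
    jsonlite::write_json(p, path, auto_unbox = TRUE, null = "null", digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_io("the 'yaml' package is required for YAML configs")
    yaml::write_yaml(p, path)
  } else stop_io(sprintf("unsupported config format '.%s'", ext))
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read config '%s'", path))
  ext <- tolower(tools::file_ext(path))
  p <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else if (ext %in% c("yaml", "yml")) {
         if (!requireNamespace("yaml", quietly = TRUE))
           stop_io("the 'yaml' package is required for YAML configs")
         yaml::read_yaml(path)
       } else stop_io(sprintf("unsupported config format '.%s'", ext))
  do.call(vessel_params, p[!vapply(p, is.null, logical(1)) | names(p) == "c"])
}

# Hash of a parameter record, for provenance columns in outputs.
params_hash <- function(params) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_params(params, f)
  unname(tools::md5sum(f))
}

# Pairs of 8-adjacent foreground pixels (linear indices, each pair once).
# Enumerates the four forward directions S, E, SE, NE in the column-major
# layout: (r, c) has linear index (c-1)*nr + r.
adjacent_pairs8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, 0, 2))
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  out <- vector("list", 4)
  dirs <- list(S = c(1L, 0L), E = c(0L, 1L), SE = c(1L, 1L), NE = c(-1L, 1L))
  for (k in seq_along(dirs)) {
    dr <- dirs[[k]][1]; dc <- dirs[[k]][2]
    ok <- r + dr >= 1L & r + dr <= nr & cc + dc >= 1L & cc + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    hit <- mask[nb]
    out[[k]] <- cbind(idx[ok][hit], nb[hit])
  }
  do.call(rbind, out)
}

# 8-connected component labeling via igraph; returns integer matrix of labels
# (0 = background).
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  pos <- integer(length(mask)); pos[idx] <- seq_along(idx)
  pr <- adjacent_pairs8(mask)
  el <- cbind(pos[pr[, 1]], pos[pr[, 2]])
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# Drop 8-connected components smaller than min_px.
remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  lab > 0L & lab %in% keep
}

#' Binarize the vessels of an mCNV lesion
#'
#' The full binarization chain: Gaussian denoising, multiscale Frangi
#' vesselness, local adaptive thresholding, intersection with the manually
#' outlined lesion mask, and removal of small speckle components. The chain is
#' deterministic: identical inputs and parameters give a bit-identical result.
#'
#' @param img An [enface_image].
#' @param lesion A [lesion_mask] congruent with `img`.
#' @param params A [vessel_params] record.
#' @return An object of class `binary_vessel_map`: list with `mask` (logical,
#'   foreground strictly inside the lesion), `lesion`, `params`,
#'   `pixel_scale_mm`.
#' @export
binarize_lesion <- function(img, lesion, params = vessel_params()) {
  if (!inherits(img, "enface_image")) stop_validation("`img` must be an enface_image")
  if (!inherits(lesion, "lesion_mask")) stop_validation("`lesion` must be a lesion_mask")
  if (!all(dim(lesion$mask) == dim(img$pixels)))
    stop_validation("image and lesion mask shapes differ")
  if (!any(lesion$mask)) stop_validation("empty lesion mask")
  den <- gaussian_denoise(img, params$sigma_px)
  vm <- if (params$threshold_on %in% c("combined", "vesselness"))
    frangi_vesselness(den, scales_px = params$scales_px, beta = params$beta,
                      c = params$c)
  fg <- switch(params$threshold_on,
    combined = local_adaptive_threshold(den, params$window_px, params$offset) &
      vm$response > params$vessel_gate * max(vm$response),
    vesselness = local_adaptive_threshold(vm, params$window_px, params$offset),
    intensity = local_adaptive_threshold(den, params$window_px, params$offset))
  fg <- fg & lesion$mask
  fg <- remove_small_objects(fg, params$min_object_px)
  structure(list(mask = fg, lesion = lesion, params = params,
                 pixel_scale_mm = img$pixel_scale_mm),
            class = "binary_vessel_map")
}

#' @export
print.binary_vessel_map <- function(x, ...) {
  cat(sprintf("<binary_vessel_map> %d vessel px in %d lesion px (density %.3f)\n",
              sum(x$mask), sum(x$lesion$mask), sum(x$mask) / sum(x$lesion$mask)))
  invisible(x)
}
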