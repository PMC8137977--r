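#' Quantify one lesion from files
#'
#' File-level wrapper around [compute_panel()]: loads an angiogram and a
#' contour, computes the nine-biomarker panel, and optionally writes a
#' one-row CSV (conventional column names plus provenance columns
#' `params_hash` and `image_path`) and the intermediate images of the chain.
#'
#' @param image_path PNG/TIFF en face angiogram.
#' @param contour_path CSV (`x,y`) or JSON lesion contour.
#' @param out_csv Optional output CSV path for the panel row.
#' @param pixel_scale_mm Pixel pitch in mm.
#' @param params A [vessel_params] record.
#' @param crt_um Optional CRT (um) to carry into the panel.
#' @param save_intermediates Optional directory; when given, writes
#'   `denoised.png`, `vesselness.png`, `binary.png`, `skeleton.png` and the
#'   graph CSV tables there.
#' @return The `biomarker_panel` (invisibly its data.frame row is written to
#'   `out_csv` when requested).
#' @export
run_quantify <- function(image_path, contour_path, out_csv = NULL,
                         pixel_scale_mm = DEFAULT_PIXEL_SCALE_MM,
                         params = vessel_params(), crt_um = NULL,
                         save_intermediates = NULL) {
  img <- load_enface_image(image_path, pixel_scale_mm)
  contour <- read_contour(contour_path)
  lesion <- rasterize_contour(contour, dim(img$pixels), pixel_scale_mm)
  if (!any(lesion$mask)) stop_validation("contour rasterizes to an empty lesion")
  panel <- compute_panel(img, lesion, params, crt_um = crt_um,
                         keep_intermediates = !is.null(save_intermediates))
  if (!is.null(save_intermediates)) {
    dir.create(save_intermediates, showWarnings = FALSE, recursive = TRUE)
    inter <- attr(panel, "intermediates")
    den <- gaussian_denoise(img, params$sigma_px)
    save_enface_png(den, file.path(save_intermediates, "denoised.png"))
    vm <- frangi_vesselness(den, params$scales_px, params$beta, params$c)
    save_enface_png(vm$response, file.path(save_intermediates, "vesselness.png"))
    write_mask_png(inter$binary$mask, file.path(save_intermediates, "binary.png"))
    write_mask_png(inter$graph$mask, file.path(save_intermediates, "skeleton.png"))
    write_graph_csv(inter$graph, save_intermediates)
    write_params(params, file.path(save_intermediates, "params.json"))
  }
  if (!is.null(out_csv)) {
    row <- as.data.frame(panel)
    row$params_hash <- attr(panel, "params_hash")
    row$image_path <- image_path
    write.csv(row, out_csv, row.names = FALSE)
  }
  panel
}

#' Simulate one synthetic lesion to files
#'
#' Generates a network, renders it, and writes `image.png`, `mask.png` and
#' `truth.json` (nodes, per-edge calibers and centerlines, and the
#' ground-truth metrics) into `out_dir`.
#'
#' @param pattern Phenotype for [generate_network()].
#' @param seed RNG seed.
#' @param out_dir Output directory.
#' @param noise Noise settings for [render_octa()].
#' @param params Optional [network_params()] overrides.
#' @return Invisibly, the file paths written.
#' @export
run_simulate <- function(pattern, seed, out_dir,
                         noise = list(speckle_sigma = 0.3,
                                      background_level = 0.12, blur_px = 0.8),
                         params = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_network(pattern, seed = seed, params = params)
  sc <- render_octa(truth, noise = noise, seed = seed)
  f_img <- file.path(out_dir, "image.png")
  f_mask <- file.path(out_dir, "mask.png")
  f_truth <- file.path(out_dir, "truth.json")
  save_enface_png(sc$image, f_img)
  write_mask_png(sc$mask, f_mask)
  jsonlite::write_json(list(
    pattern = truth$pattern, seed = truth$seed,
    pixel_scale_mm = truth$pixel_scale_mm,
    nodes = truth$nodes,
    edges = truth$edges,
    centerlines = lapply(truth$paths, function(p) unname(as.matrix(p))),
    lesion_polygon = unname(truth$lesion_polygon),
    true_metrics = unclass(truth$true_metrics)),
    f_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(image = f_img, mask = f_mask, truth = f_truth))
}

#' Run the cohort statistics layer from a manifest
#'
#' The manifest CSV has one row per eye with qualitative feature columns
#' (`OP, EC, AL, HH, FV`), an `n_injections` column, and per-timepoint
#' biomarker columns named `baseline_<m>` / `post_<m>` for each conventional
#' biomarker name (`mCNV_area, VA, VLD, FD, VD, VL, VT, VJ, JD, CRT`).
#' Writes `features.csv` (qualitative frequencies), `change_report.csv`
#' (paired summary with RR) and `correlations.csv` (percent-change Spearman
#' against CRT) into `out_dir`.
#'
#' @param manifest A path to the manifest CSV or an equivalent data.frame.
#' @param out_dir Output directory.
#' @return List with the three tables, invisibly also written as CSV.
#' @export
run_cohort <- function(manifest, out_dir) {
  man <- if (is.character(manifest)) {
    if (!file.exists(manifest)) stop_io(sprintf("manifest '%s' not found", manifest))
    read.csv(manifest)
  } else as.data.frame(manifest)
  if (nrow(man) == 0L) stop_validation("empty cohort manifest")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  feat_cols <- intersect(c("OP", "EC", "AL", "HH", "FV"), names(man))
  features <- if (length(feat_cols)) summarize_features(man[feat_cols]) else NULL
  b_cols <- grep("^baseline_", names(man), value = TRUE)
  marks <- sub("^baseline_", "", b_cols)
  marks <- marks[paste0("post_", marks) %in% names(man)]
  if (length(marks) == 0L) stop_validation("manifest has no baseline_/post_ biomarker columns")
  baseline <- setNames(man[paste0("baseline_", marks)], marks)
  post <- setNames(man[paste0("post_", marks)], marks)
  report <- build_change_report(baseline, post)
  correlations <- if ("CRT" %in% marks) correlate_percent_change(report) else NULL
  if (!is.null(features))
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(report$summary, file.path(out_dir, "change_report.csv"), row.names = FALSE)
  if (!is.null(correlations))
    write.csv(correlations, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  invisible(list(features = features, change_report = report,
                 correlations = correlations))
}
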