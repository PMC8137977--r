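scale304 <- 3 / 304

test_that("areas are pixel counts times the squared pixel pitch", {
  m <- matrix(FALSE, 304, 304); m[1:10, 1:10] <- TRUE
  expect_equal(area_mm2(m, scale304), 100 * scale304^2, tolerance = 1e-12)
  expect_equal(area_mm2(m, scale304), 0.009738, tolerance = 1e-4)
  expect_equal(area_mm2(matrix(FALSE, 10, 10), scale304), 0)
  expect_equal(area_mm2(matrix(TRUE, 304, 304), scale304), 9, tolerance = 1e-9)
})

test_that("vessel density is the vessel fraction of the lesion", {
  les <- lesion_mask(matrix(TRUE, 20, 50))
  full <- structure(list(mask = matrix(TRUE, 20, 50), lesion = les,
                         pixel_scale_mm = scale304), class = "binary_vessel_map")
  expect_equal(vessel_density(full), 1)
  none <- full; none$mask <- matrix(FALSE, 20, 50)
  expect_equal(vessel_density(none), 0)
  part <- full; part$mask[] <- FALSE; part$mask[1:11, ] <- TRUE
  # 550 of 1000 lesion px: the magnitude of a typical baseline vessel density
  expect_equal(vessel_density(part), 0.55)
  bad <- full; bad$lesion <- lesion_mask(matrix(FALSE, 20, 50))
  expect_error(vessel_density(bad), class = "octamorph_validation_error")
})

test_that("vessel diameter is area over skeleton length in um", {
  expect_equal(vessel_diameter_um(0.20, 6.96), 28.74, tolerance = 1e-2)
  expect_equal(vessel_diameter_um(0, 5), 0)
  expect_error(vessel_diameter_um(0.1, 0), class = "octamorph_undefined_marker")
  # 10 x 100 px rectangle: area / skeleton-length recovers the bar width
  # up to thinning end-erosion of the centerline
  rect <- matrix(FALSE, 30, 120); rect[11:20, 11:110] <- TRUE
  len_px <- total_length_mm(skeletonize(rect)$mask, pixel_scale_mm = 1)
  diam_px <- 1000 / len_px
  expect_gte(diam_px, 10)
  expect_lte(diam_px, 11.5)
})

test_that("box-counting dimension hits line, plane and Sierpinski values", {
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  expect_equal(fractal_dimension(line), 1, tolerance = 0.05)
  expect_equal(fractal_dimension(matrix(TRUE, 256, 256)), 2, tolerance = 0.05)
  expect_equal(fractal_dimension(fix_sierpinski(243)), log(3) / log(2),
               tolerance = 0.06)
  expect_error(fractal_dimension(matrix(FALSE, 64, 64)),
               class = "octamorph_undefined_marker")
  small <- matrix(TRUE, 12, 12)
  expect_error(fractal_dimension(small), class = "octamorph_validation_error")
})

test_that("tortuosity: straight = 1, right angle = sqrt 2 ratio, semicircle = pi/2", {
  g <- build_graph(fix_hline(60), pixel_scale_mm = 1)
  expect_equal(vessel_tortuosity(g), 1, tolerance = 1e-9)

  # right-angle branch: two 10-step legs whose length-to-chord ratio is
  # 20 / (10 * sqrt(2)); drawn as a 45-degree V so the corner pixel is not an
  # 8-adjacency triangle
  vee <- matrix(FALSE, 25, 25)
  vee[cbind(c(12:2, 3:12), c(2:12, 13:22))] <- TRUE
  gv <- build_graph(vee, prune_px = 0, pixel_scale_mm = 1)
  expect_equal(nrow(gv$branches), 1)
  expect_equal(gv$branches$path_length_px, 20 * sqrt(2), tolerance = 1e-9)
  expect_equal(vessel_tortuosity(gv), 20 / (10 * sqrt(2)), tolerance = 1e-9)
  expect_equal(vessel_tortuosity(gv), 1.414, tolerance = 1e-3)

  gs <- build_graph(fix_semicircle(40), pixel_scale_mm = 1)
  expect_equal(nrow(gs$branches), 1)
  expect_equal(vessel_tortuosity(gs), pi / 2, tolerance = 0.03 * pi / 2)

  iso <- matrix(FALSE, 9, 9); iso[5, 5] <- TRUE
  expect_error(vessel_tortuosity(build_graph(iso, pixel_scale_mm = 1)),
               class = "octamorph_undefined_marker")
})

test_that("branch path length keeps the raw step-sum while tortuosity smooths", {
  gs <- build_graph(fix_semicircle(40), pixel_scale_mm = 1)
  # raw chain arc of a digital semicircle overshoots pi*r by ~5%
  raw_tort <- vessel_tortuosity(gs, smooth_stride_px = 1)
  expect_gt(raw_tort, vessel_tortuosity(gs))
  expect_equal(gs$branches$path_length_px, raw_tort * gs$branches$chord_px,
               tolerance = 1e-9)
})

test_that("compute_panel reproduces generator truth on clean renders", {
  tr <- generate_network("medusa", seed = 2)
  sc <- render_octa(tr, noise = noise_clean(), seed = 2)
  p <- compute_panel(sc$image, sc$mask, crt_um = 310)
  tm <- tr$true_metrics
  expect_equal(p$vessel_junctions, tm$vessel_junctions)
  expect_equal(p$vessel_length_mm, tm$vessel_length_mm, tolerance = 0.05)
  expect_lt(abs(p$vessel_density - tm$vessel_density), 0.05)
  expect_equal(p$crt_um, 310)
  # panel invariants
  expect_equal(p$vessel_density, p$vessel_area_mm2 / p$mcnv_area_mm2, tolerance = 1e-12)
  expect_equal(p$junction_density_per_mm, p$vessel_junctions / p$vessel_length_mm,
               tolerance = 1e-12)
  expect_lte(p$vessel_area_mm2, p$mcnv_area_mm2)
  expect_gte(p$vessel_tortuosity, 1)
})

test_that("a zero-vessel lesion reports missing, not zero, for undefined markers", {
  img <- enface_image(matrix(0, 60, 60), normalize = FALSE)
  les <- rasterize_contour(cbind(c(10, 50, 50, 10), c(10, 10, 50, 50)), c(60, 60))
  p <- compute_panel(img, les)
  expect_equal(p$vessel_area_mm2, 0)
  expect_equal(p$vessel_length_mm, 0)
  expect_equal(p$vessel_junctions, 0)
  expect_true(is.na(p$vessel_diameter_um))
  expect_true(is.na(p$fractal_dimension))
  expect_true(is.na(p$vessel_tortuosity))
  expect_true(is.na(p$junction_density_per_mm))
  expect_setequal(intersect(attr(p, "undefined"),
                            c("vessel_diameter_um", "fractal_dimension",
                              "vessel_tortuosity", "junction_density_per_mm")),
                  c("vessel_diameter_um", "fractal_dimension",
                    "vessel_tortuosity", "junction_density_per_mm"))
})

test_that("panels are deterministic across repeated runs", {
  tr <- generate_network("sea_fan", seed = 4)
  sc1 <- render_octa(tr, noise = noise_default(), seed = 4)
  sc2 <- render_octa(tr, noise = noise_default(), seed = 4)
  expect_identical(sc1$image$pixels, sc2$image$pixels)
  p1 <- as.data.frame(compute_panel(sc1$image, sc1$mask))
  p2 <- as.data.frame(compute_panel(sc2$image, sc2$mask))
  expect_identical(p1, p2)
})

test_that("doubling the pixel scale doubles lengths and quadruples areas only", {
  tr <- generate_network("tree_in_bud", seed = 1)
  sc <- render_octa(tr, noise = noise_clean(), seed = 1)
  p1 <- compute_panel(sc$image, sc$mask)
  img2 <- enface_image(sc$image$pixels, pixel_scale_mm = 2 * scale304,
                       normalize = FALSE)
  les2 <- lesion_mask(sc$mask$mask, pixel_scale_mm = 2 * scale304)
  p2 <- compute_panel(img2, les2)
  expect_equal(p2$vessel_length_mm, 2 * p1$vessel_length_mm, tolerance = 1e-9)
  expect_equal(p2$mcnv_area_mm2, 4 * p1$mcnv_area_mm2, tolerance = 1e-9)
  expect_equal(p2$vessel_area_mm2, 4 * p1$vessel_area_mm2, tolerance = 1e-9)
  expect_equal(p2$vessel_density, p1$vessel_density, tolerance = 1e-9)
  expect_equal(p2$fractal_dimension, p1$fractal_dimension, tolerance = 1e-9)
  expect_equal(p2$vessel_tortuosity, p1$vessel_tortuosity, tolerance = 1e-9)
  expect_equal(p2$vessel_junctions, p1$vessel_junctions)
})

test_that("the panel data.frame uses the conventional report columns", {
  tr <- generate_network("medusa", seed = 6)
  sc <- render_octa(tr, noise = noise_clean(), seed = 6)
  df <- as.data.frame(compute_panel(sc$image, sc$mask, crt_um = 300))
  expect_named(df, c("mCNV_area", "VA", "VLD", "FD", "VD", "VL", "VT", "VJ",
                     "JD", "CRT"))
})
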