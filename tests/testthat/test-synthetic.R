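test_that("generation is deterministic per seed and validates the pattern", {
  t1 <- generate_network("medusa", seed = 7)
  t2 <- generate_network("medusa", seed = 7)
  expect_identical(t1$edges, t2$edges)
  expect_identical(t1$paths, t2$paths)
  expect_identical(as.data.frame(t1$true_metrics), as.data.frame(t2$true_metrics))
  expect_false(identical(t1$edges, generate_network("medusa", seed = 8)$edges))
  expect_error(generate_network("spiral", seed = 1),
               class = "octamorph_validation_error")
})

test_that("sea-fan primaries originate within a 60-degree boundary sector", {
  for (s in 1:5) {
    tr <- generate_network("sea_fan", seed = s)
    a <- tr$primary_origin_deg
    spread <- diff(range((a - a[1] + 180) %% 360))   # unwrap around the first
    expect_lte(spread, 60)
  }
})

test_that("disorganized-loop networks contain anastomotic cycles", {
  n_cyc <- 0L
  for (s in 1:5) {
    tr <- generate_network("disorganized_loops", seed = s)
    g <- igraph::graph_from_edgelist(cbind(tr$edges$from, tr$edges$to),
                                     directed = FALSE)
    if (igraph::ecount(g) > igraph::vcount(g) - igraph::count_components(g))
      n_cyc <- n_cyc + 1L
  }
  expect_gte(n_cyc, 4)   # a loop-free draw is possible but must be rare
})

test_that("centerlines stay inside the lesion polygon", {
  tr <- generate_network("medusa", seed = 9)
  pts <- do.call(rbind, tr$paths)
  inside <- octamorph:::point_in_polygon(pts[, 1], pts[, 2],
                                         tr$lesion_polygon[, 1],
                                         tr$lesion_polygon[, 2])
  expect_true(all(inside))
})

test_that("ground-truth metrics are internally consistent", {
  tr <- generate_network("tree_in_bud", seed = 3)
  tm <- tr$true_metrics
  arcs <- sum(vapply(tr$paths, octamorph:::polyline_length, numeric(1)))
  expect_equal(tm$vessel_length_mm, arcs * tr$pixel_scale_mm, tolerance = 1e-12)
  degs <- octamorph:::node_degrees(tr)
  expect_equal(tm$vessel_junctions, sum(degs >= 3))
  expect_equal(tm$junction_density_per_mm,
               tm$vessel_junctions / tm$vessel_length_mm, tolerance = 1e-12)
  expect_equal(tm$vessel_density, tm$vessel_area_mm2 / tm$mcnv_area_mm2,
               tolerance = 1e-12)
  expect_gte(tm$vessel_tortuosity, 1)
})

test_that("anti-VEGF transform: identity, pruning direction, and emptying", {
  tr <- generate_network("medusa", seed = 5)
  same <- apply_anti_vegf(tr, prune_caliber_px = 0, trunk_dilation = 1)
  expect_equal(as.data.frame(same$true_metrics), as.data.frame(tr$true_metrics),
               tolerance = 1e-9)

  med <- median(tr$edges$caliber_px)
  post <- apply_anti_vegf(tr, prune_caliber_px = med, trunk_dilation = 1.15)
  expect_lt(post$true_metrics$vessel_junctions, tr$true_metrics$vessel_junctions)
  expect_gt(min(post$edges$caliber_px) / 1.15, min(tr$edges$caliber_px))
  expect_gt(mean(post$edges$caliber_px), mean(tr$edges$caliber_px))

  gone <- apply_anti_vegf(tr, prune_caliber_px = max(tr$edges$caliber_px) + 1)
  expect_equal(nrow(gone$edges), 0)
  expect_equal(gone$true_metrics$vessel_length_mm, 0)
  expect_equal(gone$true_metrics$vessel_junctions, 0)
  expect_true(is.na(gone$true_metrics$vessel_diameter_um))
})

test_that("pruning moves every biomarker in the treated direction", {
  for (s in 1:5) {
    tr <- generate_network("medusa", seed = s)
    thr <- quantile(tr$edges$caliber_px, 0.65, names = FALSE)
    post <- apply_anti_vegf(tr, thr, trunk_dilation = 1.15)
    b <- tr$true_metrics; a <- post$true_metrics
    expect_lt(a$mcnv_area_mm2, b$mcnv_area_mm2)
    expect_lt(a$vessel_area_mm2, b$vessel_area_mm2)
    expect_lt(a$vessel_length_mm, b$vessel_length_mm)
    expect_lt(a$vessel_junctions, b$vessel_junctions)
    expect_lt(a$fractal_dimension, b$fractal_dimension)
    expect_lt(a$junction_density_per_mm, b$junction_density_per_mm)
    expect_gte(a$vessel_diameter_um, b$vessel_diameter_um)
  }
})

test_that("rendering is seed-deterministic and respects the noise model", {
  tr <- generate_network("sea_fan", seed = 6)
  s1 <- render_octa(tr, noise = noise_default(), seed = 11)
  s2 <- render_octa(tr, noise = noise_default(), seed = 11)
  expect_identical(s1$image$pixels, s2$image$pixels)
  s3 <- render_octa(tr, noise = noise_default(), seed = 12)
  expect_false(identical(s1$image$pixels, s3$image$pixels))

  clean <- render_octa(tr, noise = noise_clean(), seed = 1)
  expect_setequal(unique(as.vector(clean$image$pixels)), c(0, 1))
  expect_error(render_octa(apply_anti_vegf(tr, 99), seed = 1),
               class = "octamorph_validation_error")
})

test_that("the pipeline recovers junctions within 15% under default speckle", {
  for (pat in c("medusa", "tree_in_bud")) {
    for (s in 1:3) {
      tr <- generate_network(pat, seed = s)
      sc <- render_octa(tr, noise = noise_default(), seed = s)
      p <- compute_panel(sc$image, sc$mask)
      tm <- tr$true_metrics
      expect_lte(abs(p$vessel_junctions - tm$vessel_junctions),
                 ceiling(0.15 * tm$vessel_junctions))
      expect_equal(p$vessel_length_mm, tm$vessel_length_mm, tolerance = 0.10)
      expect_equal(p$vessel_tortuosity, tm$vessel_tortuosity, tolerance = 0.1)
    }
  }
})

test_that("fractal dimension of the truth rises with branching probability", {
  lo <- generate_network("medusa", seed = 21,
                         params = network_params("medusa", branching_prob = 0.25,
                                                 max_depth = 2))
  hi <- generate_network("medusa", seed = 21,
                         params = network_params("medusa", branching_prob = 1,
                                                 max_depth = 3))
  expect_gt(hi$true_metrics$fractal_dimension, lo$true_metrics$fractal_dimension)
})

test_that("a simulated cohort lands in the clinical value range and responds", {
  sim <- simulate_cohort(n_eyes = 12, seed = 2)
  expect_equal(nrow(sim$baseline), 12)
  expect_true(all(sim$meta$OP %in% c("OI", "DVL")))
  expect_true(all(sim$baseline$VT > 1 & sim$baseline$VT < 1.6))
  expect_true(all(sim$baseline$VLD > 0.05 & sim$baseline$VLD < 0.7))
  r <- build_change_report(sim$baseline, sim$post)
  s <- r$summary
  expect_lt(s$rr_pct[s$biomarker == "VJ"], 100)
  expect_lt(s$rr_pct[s$biomarker == "VL"], 100)
  expect_gte(s$rr_pct[s$biomarker == "VD"], 100)
})
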