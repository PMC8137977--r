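test_that("thinning reduces a solid bar to its 1-px centerline", {
  bar <- matrix(FALSE, 30, 120); bar[13:17, 11:110] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(sk$mask[!bar] == FALSE))                 # skeleton inside parent
  expect_equal(length(unique(which(sk$mask, arr.ind = TRUE)[, 1])), 1)
  len <- total_length_mm(sk$mask, pixel_scale_mm = 1)
  # 99 steps minus thinning end-erosion of about half the bar width per end
  expect_gte(len, 99 - 6)
  expect_lte(len, 99)
})

test_that("thinning keeps single pixels and empty masks", {
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_identical(skeletonize(one)$mask, one)
  expect_equal(sum(skeletonize(matrix(FALSE, 5, 5))$mask), 0)
})

test_that("thinning is idempotent and at its removable-pixel fixed point", {
  set.seed(3)
  blob <- matrix(runif(40 * 40) > 0.45, 40, 40)
  sk1 <- skeletonize(blob)
  expect_identical(skeletonize(sk1$mask)$mask, sk1$mask)
  tr <- generate_network("sea_fan", seed = 2)
  m <- octamorph:::rasterize_tubes(tr)$tube
  sk <- skeletonize(m)
  expect_identical(skeletonize(sk$mask)$mask, sk$mask)
})

test_that("a thick plus-sign yields exactly one junction cluster", {
  g <- build_graph(skeletonize(fix_plus_thick()), pixel_scale_mm = 1)
  expect_equal(junction_count(g), 1)
  expect_gte(junction_count(g, "pixels"), 1)   # raw-pixel convention >= clusters
  expect_equal(nrow(g$endpoints), 4)
})

test_that("a T of three arms gives 1 junction, 3 endpoints, 3 branches", {
  g <- build_graph(fix_T(), prune_px = 3, pixel_scale_mm = 1)
  expect_equal(junction_count(g), 1)
  expect_equal(nrow(g$endpoints), 3)
  expect_equal(nrow(g$branches), 3)
})

test_that("a straight line gives 0 junctions, 2 endpoints, 1 straight branch", {
  g <- build_graph(fix_hline(50), pixel_scale_mm = 1)
  expect_equal(junction_count(g), 0)
  expect_equal(nrow(g$endpoints), 2)
  expect_equal(nrow(g$branches), 1)
  expect_equal(g$branches$path_length_px, g$branches$chord_px, tolerance = 1e-12)
})

test_that("a discrete ring is a single cycle branch", {
  g <- build_graph(fix_ring(20), pixel_scale_mm = 1)
  expect_equal(junction_count(g), 0)
  expect_equal(nrow(g$endpoints), 0)
  expect_equal(nrow(g$branches), 1)
  expect_true(g$branches$is_cycle)
  # cycle chord convention: the loop diameter
  expect_equal(g$branches$chord_px, 40, tolerance = 1)
})

test_that("total length follows the 1 / sqrt(2) step rule", {
  expect_equal(total_length_mm(fix_hline(101), pixel_scale_mm = 3 / 304),
               100 * 3 / 304, tolerance = 1e-12)
  expect_equal(total_length_mm(fix_hline(101), pixel_scale_mm = 3 / 304),
               0.9868, tolerance = 1e-3)
  expect_equal(total_length_mm(fix_diag(101), pixel_scale_mm = 3 / 304),
               100 * sqrt(2) * 3 / 304, tolerance = 1e-12)
  expect_equal(total_length_mm(matrix(FALSE, 10, 10), pixel_scale_mm = 1), 0)
})

test_that("branch lengths plus internal cluster length account for the total exactly", {
  for (s in c(2, 4)) {
    tr <- generate_network("medusa", seed = s)
    sk <- skeletonize(octamorph:::rasterize_tubes(tr)$tube)
    g <- build_graph(sk, prune_px = 0, merge_junction_px = 0)
    expect_equal(sum(g$branches$path_length_mm) + g$internal_length_mm,
                 total_length_mm(g$mask, pixel_scale_mm = tr$pixel_scale_mm),
                 tolerance = 1e-9)
    # pruning/merging moves length between the two terms, never loses it
    g2 <- build_graph(sk)
    expect_equal(sum(g2$branches$path_length_mm) + g2$internal_length_mm,
                 total_length_mm(g2$mask, pixel_scale_mm = tr$pixel_scale_mm),
                 tolerance = 1e-9)
  }
})

test_that("branch paths, junction pixels and isolated points cover the skeleton", {
  tr <- generate_network("disorganized_loops", seed = 2)
  sk <- skeletonize(octamorph:::rasterize_tubes(tr)$tube)
  g <- build_graph(sk, prune_px = 0, merge_junction_px = 0)
  m <- g$mask
  # independent degree map by direct neighbor counting
  deg <- matrix(0L, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(FALSE, nrow(m), ncol(m))
    rs <- max(1, 1 + dr):min(nrow(m), nrow(m) + dr)
    cs <- max(1, 1 + dc):min(ncol(m), ncol(m) + dc)
    sh[rs, cs] <- m[rs - dr, cs - dc]
    deg <- deg + (sh & m)
  }
  covered <- matrix(FALSE, nrow(m), ncol(m))
  for (p in g$paths) covered[p] <- TRUE
  covered[m & deg >= 3] <- TRUE   # junction pixels (branch terminals included)
  covered[m & deg == 0] <- TRUE   # isolated points
  expect_true(all(covered[m]))
  expect_equal(sum(g$junctions$n_px), sum(m & deg >= 3))
  expect_equal(g$n_isolated, sum(m & deg == 0))
})

test_that("junction count on clean synthetic trees equals the generator truth", {
  for (s in 1:3) {
    tr <- generate_network("tree_in_bud", seed = s)
    g <- build_graph(skeletonize(octamorph:::rasterize_tubes(tr)$tube))
    expect_equal(junction_count(g), tr$true_metrics$vessel_junctions)
  }
})

test_that("spur pruning removes tip-forks but keeps real junction arms", {
  # a diagonal branch whose end splits into two 2-px prongs (the classic
  # thinning artifact at a rounded vessel tip)
  m <- matrix(FALSE, 28, 28)
  m[cbind(5:20, 5:20)] <- TRUE
  m[cbind(c(21, 22), c(21, 22))] <- TRUE     # prong A
  m[cbind(c(19, 18), c(21, 22))] <- TRUE     # prong B
  g0 <- build_graph(m, prune_px = 0, pixel_scale_mm = 1)
  expect_equal(junction_count(g0), 1)        # without pruning the fork counts
  expect_equal(nrow(g0$endpoints), 3)
  g <- build_graph(m, prune_px = 3, pixel_scale_mm = 1)
  expect_equal(junction_count(g), 0)         # a pruned tip-fork is no junction
  expect_equal(nrow(g$endpoints), 2)

  # a 2-px stub on a long vessel is kept: pruning it would demote a
  # three-connection node whose other arms are both long (the orphaned-stub
  # configuration seen at shallow-angle bifurcations)
  m2 <- matrix(FALSE, 30, 30)
  m2[cbind(5:25, 5:25)] <- TRUE              # long vessel
  m2[cbind(c(14, 13), c(16, 17))] <- TRUE    # short stub at mid-vessel
  gk <- build_graph(m2, prune_px = 3, pixel_scale_mm = 1)
  expect_equal(junction_count(gk), 1)
  expect_equal(nrow(gk$endpoints), 3)

  # at a 4-connection cluster the same stub is pruned and the junction stays
  m3 <- matrix(FALSE, 30, 30)
  m3[cbind(5:15, 5:15)] <- TRUE              # parent
  m3[cbind(16:25, 16:25)] <- TRUE            # child 1 (continuation)
  m3[cbind(16:25, 14:5)] <- TRUE             # child 2 (other diagonal)
  m3[cbind(c(14, 13), c(16, 17))] <- TRUE    # parasitic stub at the node
  gm <- build_graph(m3, prune_px = 3, pixel_scale_mm = 1)
  expect_equal(junction_count(gm), 1)
  expect_equal(nrow(gm$endpoints), 3)        # the stub endpoint is gone
})

test_that("graph tables export to CSV", {
  g <- build_graph(fix_T(), pixel_scale_mm = 1)
  d <- tempfile()
  write_graph_csv(g, d)
  nodes <- read.csv(file.path(d, "nodes.csv"))
  br <- read.csv(file.path(d, "branches.csv"))
  expect_equal(sum(nodes$type == "junction"), 1)
  expect_equal(sum(nodes$type == "endpoint"), 3)
  expect_equal(nrow(br), 3)
  expect_true(all(c("node_a", "node_b", "path_length_mm") %in% names(br)))
  unlink(d, recursive = TRUE)
})
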