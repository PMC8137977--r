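# Synthetic OCTA-like CNV networks with exact ground truth. Networks are
# planar graphs of nodes and polyline edges grown by depth-limited recursive
# bifurcation with Gaussian-perturbed step directions and exponential caliber
# decay; an anastomosis step can splice endpoints into other branches to form
# loops. Candidate steps that would bring a branch too close to an unrelated
# branch are rejected, so centerlines never overlap and the ground-truth
# junction count is well defined on the rendered image.

#' Generator parameters for a synthetic CNV network
#'
#' Defaults depend on the phenotype and were chosen once to produce lesions in
#' the size range of clinical mCNV on a 3 x 3 mm field (lesion area a few
#' tenths of a mm^2, a few dozen junctions, calibers 20-40 um).
#'
#' @param pattern One of `"medusa"`, `"sea_fan"`, `"tree_in_bud"`,
#'   `"disorganized_loops"`.
#' @param ... Overrides for any of: `n_primary_branches`, `branching_prob`,
#'   `max_depth`, `caliber_root_px`, `caliber_decay`, `loop_prob`,
#'   `lesion_radius_px`, `branch_len_px`, `len_decay`, `step_px`,
#'   `wiggle_sd_deg`, `branch_angle_deg`, `shape`.
#' @return A named list of parameters.
#' @export
network_params <- function(pattern = c("medusa", "sea_fan", "tree_in_bud",
                                       "disorganized_loops"), ...) {
  pattern <- tryCatch(match.arg(pattern),
                      error = function(e) stop_validation(
                        sprintf("unknown pattern '%s'", paste(pattern, collapse = "/"))))
  p <- switch(pattern,
    medusa = list(n_primary_branches = 5, branching_prob = 0.85, max_depth = 3,
                  caliber_root_px = 4, caliber_decay = 0.75, loop_prob = 0,
                  lesion_radius_px = 95, branch_len_px = 32, len_decay = 0.85,
                  step_px = 5, wiggle_sd_deg = 7, branch_angle_deg = 32),
    sea_fan = list(n_primary_branches = 4, branching_prob = 0.85, max_depth = 3,
                   caliber_root_px = 4, caliber_decay = 0.75, loop_prob = 0,
                   lesion_radius_px = 95, branch_len_px = 34, len_decay = 0.85,
                   step_px = 5, wiggle_sd_deg = 7, branch_angle_deg = 30),
    tree_in_bud = list(n_primary_branches = 6, branching_prob = 0.9, max_depth = 2,
                       caliber_root_px = 3.5, caliber_decay = 0.78, loop_prob = 0,
                       lesion_radius_px = 80, branch_len_px = 24, len_decay = 0.85,
                       step_px = 5, wiggle_sd_deg = 8, branch_angle_deg = 34),
    disorganized_loops = list(n_primary_branches = 4, branching_prob = 0.7,
                              max_depth = 2, caliber_root_px = 3,
                              caliber_decay = 0.8, loop_prob = 0.5,
                              lesion_radius_px = 65, branch_len_px = 20,
                              len_decay = 0.9, step_px = 5, wiggle_sd_deg = 12,
                              branch_angle_deg = 36))
  p$shape <- c(304L, 304L)
  p$caliber_min_px <- 1.2
  over <- list(...)
  bad <- setdiff(names(over), c(names(p)))
  if (length(bad)) stop_validation(sprintf("unknown parameter(s): %s",
                                           paste(bad, collapse = ", ")))
  p[names(over)] <- over
  p
}

deg2rad <- function(d) d * pi / 180

#' Generate a synthetic CNV network with ground truth
#'
#' Grows a seeded stochastic vessel network in one of the four clinical
#' phenotypes: `medusa` (branches radiate in all directions from the lesion
#' center), `sea_fan` (branches radiate from one side, their origins confined
#' to a 60-degree sector of the lesion boundary), `tree_in_bud` (a compact
#' round lesion without a dominant trunk), and `disorganized_loops` (short
#' segments with anastomotic loops and few ramifications).
#'
#' @param pattern Phenotype name.
#' @param seed Integer RNG seed; the same seed reproduces the network
#'   exactly.
#' @param params A [network_params()] list.
#' @param pixel_scale_mm Physical pixel pitch.
#' @return An object of class `vessel_network_truth`: nodes, polyline edges
#'   with per-edge caliber, the lesion hull polygon, the pattern, seed,
#'   root-node ids, and `true_metrics` — the ground-truth biomarker panel
#'   computed from the continuous centerlines (lengths, junctions,
#'   tortuosity) and their rasterized tube union (areas, fractal dimension).
#' @export
generate_network <- function(pattern = c("medusa", "sea_fan", "tree_in_bud",
                                         "disorganized_loops"),
                             seed = 1, params = NULL,
                             pixel_scale_mm = DEFAULT_PIXEL_SCALE_MM) {
  pattern <- tryCatch(match.arg(pattern),
                      error = function(e) stop_validation(
                        sprintf("unknown pattern '%s'", paste(pattern, collapse = "/"))))
  params <- params %||% network_params(pattern)
  with_seed(seed, {
    ctr <- c(params$shape[2] / 2, params$shape[1] / 2)   # (x, y)
    R <- params$lesion_radius_px

    nodes_x <- numeric(); nodes_y <- numeric()
    add_node <- function(x, y) {
      nodes_x[length(nodes_x) + 1L] <<- x
      nodes_y[length(nodes_y) + 1L] <<- y
      length(nodes_x)
    }
    edges <- list()   # list of list(from, to, caliber, depth, path)
    edge_from <- integer(); edge_to <- integer()
    pool <- matrix(numeric(0), 0, 4)  # x, y, edge id, caliber

    grow_branch <- function(from_node, dir, depth, caliber, len) {
      o <- c(nodes_x[from_node], nodes_y[from_node])
      pts <- matrix(o, 1, 2)
      n_steps <- max(2L, round(len / params$step_px))
      # points of edges meeting at the origin node are exempt from the
      # clearance test, but only close to the shared node itself
      exempt_eid <- which(edge_from == from_node | edge_to == from_node)
      for (i in seq_len(n_steps)) {
        dir <- dir + rnorm(1, 0, deg2rad(params$wiggle_sd_deg))
        cand <- pts[nrow(pts), ] + params$step_px * c(cos(dir), sin(dir))
        if (sqrt(sum((cand - ctr)^2)) > R - caliber) break
        if (nrow(pool)) {
          d2 <- (pool[, 1] - cand[1])^2 + (pool[, 2] - cand[2])^2
          clear <- (caliber + pool[, 4]) / 2 + 3
          # the shared-node exemption only covers the first steps out of the
          # node; later steps treat parent and siblings as obstacles, so a
          # recurving branch cannot brush them
          exempt <- (i <= 2L) & pool[, 3] %in% exempt_eid &
            (pool[, 1] - o[1])^2 + (pool[, 2] - o[2])^2 < (2 * params$step_px)^2
          if (any(d2 < clear^2 & !exempt)) break
        }
        pts <- rbind(pts, cand)
      }
      # a branch must clear at least three steps; shorter stubs sit below
      # raster resolution (their skeleton arms would vanish into the
      # junction blob and the spur pruner)
      if (nrow(pts) < 4L) return(NULL)
      to <- add_node(pts[nrow(pts), 1], pts[nrow(pts), 2])
      eid <- length(edges) + 1L
      edges[[eid]] <<- list(from = from_node, to = to, caliber = caliber,
                            depth = depth, path = pts)
      edge_from[eid] <<- from_node; edge_to[eid] <<- to
      # register at half-step resolution so clearance tests approximate
      # point-to-curve distance
      mid <- (pts[-1, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
      reg <- rbind(pts[-1, , drop = FALSE], mid)
      pool <<- rbind(pool, cbind(reg[, 1], reg[, 2], eid, caliber))
      list(node = to, dir = dir, eid = eid)
    }

    # seed the growth queue per phenotype
    queue <- list()
    roots <- integer()
    primary_origin_deg <- numeric()
    grow_all <- function() {
      nodes_x <<- numeric(); nodes_y <<- numeric()
      edges <<- list(); edge_from <<- integer(); edge_to <<- integer()
      pool <<- matrix(numeric(0), 0, 4)
      roots <<- integer(); primary_origin_deg <<- numeric()
      queue <- list()
      if (pattern == "medusa") {
        root <- add_node(ctr[1] + rnorm(1, 0, 2), ctr[2] + rnorm(1, 0, 2))
        roots <<- root
        base <- runif(1, 0, 2 * pi)
        for (k in seq_len(params$n_primary_branches)) {
          ang <- base + 2 * pi * (k - 1) / params$n_primary_branches +
            rnorm(1, 0, deg2rad(6))
          queue[[length(queue) + 1L]] <- list(node = root, dir = ang, depth = 0L,
            caliber = params$caliber_root_px, len = params$branch_len_px)
        }
      } else if (pattern == "sea_fan") {
        phi0 <- runif(1, 0, 2 * pi)
        for (k in seq_len(params$n_primary_branches)) {
          phi <- phi0 + deg2rad(runif(1, -25, 25))   # inside a 60 deg sector
          primary_origin_deg[k] <<- phi * 180 / pi
          ox <- ctr[1] + 0.95 * R * cos(phi)
          oy <- ctr[2] + 0.95 * R * sin(phi)
          root <- add_node(ox, oy)
          roots <<- c(roots, root)
          inward <- atan2(ctr[2] - oy, ctr[1] - ox) + deg2rad(runif(1, -20, 20))
          queue[[length(queue) + 1L]] <- list(node = root, dir = inward, depth = 0L,
            caliber = params$caliber_root_px, len = params$branch_len_px)
        }
      } else {  # tree_in_bud and disorganized_loops: scattered short trunks
        rmax <- if (pattern == "tree_in_bud") 0.35 * R else 0.3 * R
        placed <- matrix(numeric(0), 0, 2)
        for (k in seq_len(params$n_primary_branches)) {
          for (try in 1:30) {
            a <- runif(1, 0, 2 * pi); rr <- rmax * sqrt(runif(1))
            cand <- ctr + rr * c(cos(a), sin(a))
            if (!nrow(placed) ||
                min((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2) >
                  (3.5 * params$caliber_root_px)^2) break
          }
          placed <- rbind(placed, cand)
          root <- add_node(cand[1], cand[2])
          roots <<- c(roots, root)
          queue[[length(queue) + 1L]] <- list(node = root, dir = runif(1, 0, 2 * pi),
            depth = 0L, caliber = params$caliber_root_px,
            len = params$branch_len_px)
        }
      }
      while (length(queue)) {
        it <- queue[[1]]; queue[[1]] <- NULL
        res <- grow_branch(it$node, it$dir, it$depth, it$caliber, it$len)
        if (is.null(res)) next
        child_cal <- max(params$caliber_min_px, it$caliber * params$caliber_decay)
        if (it$depth < params$max_depth &&
            runif(1) < params$branching_prob) {
          # clamp so neither child runs back down the parent tube
          spread <- deg2rad(pmin(pmax(params$branch_angle_deg + rnorm(2, 0, 8),
                                      20), 55))
          for (s in c(-1, 1)) {
            queue[[length(queue) + 1L]] <- list(node = res$node,
              dir = res$dir + s * spread[(s + 3) / 2], depth = it$depth + 1L,
              caliber = child_cal, len = it$len * params$len_decay)
          }
        }
      }
    }
    # a cramped draw can fizzle into a couple of stubs; regrow (the RNG
    # stream continues, so this stays deterministic per seed)
    for (attempt in 1:6) {
      grow_all()
      if (length(edges) >= 4L) break
    }

    truth <- structure(list(
      nodes = data.frame(id = seq_along(nodes_x), x = nodes_x, y = nodes_y),
      edges = data.frame(
        id = seq_along(edges),
        from = vapply(edges, `[[`, integer(1), "from"),
        to = vapply(edges, `[[`, integer(1), "to"),
        caliber_px = vapply(edges, `[[`, numeric(1), "caliber"),
        depth = vapply(edges, `[[`, integer(1), "depth")),
      paths = lapply(edges, `[[`, "path"),
      pattern = pattern, seed = seed, roots = roots,
      primary_origin_deg = primary_origin_deg,
      params = params, pixel_scale_mm = pixel_scale_mm,
      shape = params$shape, lesion_polygon = NULL, true_metrics = NULL),
      class = "vessel_network_truth")
    if (pattern == "disorganized_loops" && params$loop_prob > 0) {
      truth <- add_anastomoses(truth, params$loop_prob)
      if (!truth_has_cycle(truth))
        truth <- add_anastomoses(truth, params$loop_prob, force = TRUE)
    }
    finalize_truth(truth)
  })
}

truth_has_cycle <- function(truth) {
  if (nrow(truth$edges) == 0L) return(FALSE)
  g <- igraph::graph_from_edgelist(cbind(truth$edges$from, truth$edges$to),
                                   directed = FALSE)
  igraph::ecount(g) > igraph::vcount(g) - igraph::count_components(g)
}

# Splice free endpoints into nearby branches, creating loops and T-junctions.
# Loop formation prefers joining two free endpoints (a smooth vessel loop,
# no new junction); a second pass runs unconditionally if chance left the
# network loop-free, since a loop is what defines this phenotype.
# Must run inside the generator's seeded RNG context.
add_anastomoses <- function(truth, loop_prob, force = FALSE) {
  degs <- node_degrees(truth)
  endpoints <- which(degs == 1L & !(seq_along(degs) %in% truth$roots))
  for (ep in endpoints) {
    if (force && truth_has_cycle(truth)) break
    if (!force && runif(1) >= loop_prob) next
    degs <- node_degrees(truth)                  # refresh after earlier splices
    if (degs[ep] != 1L) next
    p0 <- c(truth$nodes$x[ep], truth$nodes$y[ep])
    inc <- which(truth$edges$from == ep | truth$edges$to == ep)
    # preferred closure: join two free endpoints (forms a loop with no new
    # junction, so the raster stays unambiguous)
    others <- setdiff(which(degs == 1L & !(seq_along(degs) %in% truth$roots)), ep)
    if (length(others)) {
      d2 <- sqrt((truth$nodes$x[others] - p0[1])^2 +
                 (truth$nodes$y[others] - p0[2])^2)
      ord <- others[order(d2)]
      d2 <- sort(d2)
      joined <- FALSE
      for (k in seq_along(ord)) {
        if (d2[k] < 2 * truth$params$step_px || d2[k] > 13 * truth$params$step_px) next
        ep2 <- ord[k]
        inc2 <- which(truth$edges$from == ep2 | truth$edges$to == ep2)
        p1 <- c(truth$nodes$x[ep2], truth$nodes$y[ep2])
        # the connector must continue each branch forward; a hairpin fold
        # would collapse into one thick tube on the raster
        tip_dir <- function(node, eid) {
          pa <- truth$paths[[eid]]
          tip <- if (truth$edges$to[eid] == node) pa[nrow(pa), ] - pa[nrow(pa) - 1L, ]
                 else pa[1, ] - pa[2, ]
          tip / sqrt(sum(tip^2))
        }
        u0 <- tip_dir(ep, inc[1]); u1 <- tip_dir(ep2, inc2[1])
        # cubic Bezier that leaves each tip along its own branch direction,
        # so the loop continues both vessels smoothly instead of folding
        # back into them
        h <- 0.5 * d2[k]
        cp1 <- p0 + h * u0
        cp2 <- p1 + h * u1
        n_seg <- max(6L, 2L * ceiling(d2[k] / truth$params$step_px))
        t <- seq(0, 1, length.out = n_seg)
        conn <- cbind(
          (1 - t)^3 * p0[1] + 3 * (1 - t)^2 * t * cp1[1] +
            3 * (1 - t) * t^2 * cp2[1] + t^3 * p1[1],
          (1 - t)^3 * p0[2] + 3 * (1 - t)^2 * t * cp1[2] +
            3 * (1 - t) * t^2 * cp2[2] + t^3 * p1[2])
        if (any(conn < 4) || any(conn[, 1] > truth$shape[2] - 4) ||
            any(conn[, 2] > truth$shape[1] - 4)) next
        cal_conn <- max(truth$params$caliber_min_px,
                        0.9 * min(truth$edges$caliber_px[c(inc, inc2)]))
        clash <- FALSE
        for (ei in seq_along(truth$paths)) {
          path <- truth$paths[[ei]]
          clear <- (truth$edges$caliber_px[ei] + cal_conn) / 2 + 2
          if (ei %in% c(inc, inc2)) {
            # the arc may touch its own tips but must not pinch back onto
            # the incident branches further along
            keep <- 4:(n_seg - 3)
            if (length(keep) < 2) next
            dmin <- min(outer(conn[keep, 1], path[, 1], `-`)^2 +
                        outer(conn[keep, 2], path[, 2], `-`)^2)
            near_tip <- min((path[, 1] - p0[1])^2 + (path[, 2] - p0[2])^2,
                            (path[, 1] - p1[1])^2 + (path[, 2] - p1[2])^2)
            if (dmin < (0.8 * clear)^2 && dmin < near_tip) { clash <- TRUE; break }
          } else {
            dmin <- min(outer(conn[, 1], path[, 1], `-`)^2 +
                        outer(conn[, 2], path[, 2], `-`)^2)
            if (dmin < clear^2) { clash <- TRUE; break }
          }
        }
        if (clash) next
        cid <- nrow(truth$edges) + 1L
        truth$edges <- rbind(truth$edges,
          data.frame(id = cid, from = ep, to = ep2, caliber_px = cal_conn,
                     depth = max(truth$edges$depth)))
        truth$paths[[cid]] <- conn
        joined <- TRUE
        break
      }
      if (joined) next
    }
    # the new junction must stay clear of nodes that are visible on the
    # raster (junctions and endpoint caps); pass-through joints do not matter
    vis <- which(degs != 2L)
    cand <- NULL
    for (ei in seq_along(truth$paths)) {
      if (ei %in% inc) next
      path <- truth$paths[[ei]]
      if (nrow(path) < 3L) next                  # no interior vertex to splice at
      iv <- 2:(nrow(path) - 1)
      dn <- sqrt(outer(path[iv, 1], truth$nodes$x[vis], `-`)^2 +
                 outer(path[iv, 2], truth$nodes$y[vis], `-`)^2)
      iv <- iv[apply(dn, 1, min) >= 2 * truth$params$step_px]
      if (!length(iv)) next
      d <- sqrt((path[iv, 1] - p0[1])^2 + (path[iv, 2] - p0[2])^2)
      ok <- d >= truth$params$step_px & d <= 8 * truth$params$step_px
      if (any(ok))
        cand <- rbind(cand, cbind(eid = ei, vertex = iv[ok], d = d[ok]))
    }
    if (is.null(cand)) next
    cand <- cand[order(cand[, "d"]), , drop = FALSE]
    # take the nearest candidate whose connector does not graze an
    # uninvolved branch
    for (k in seq_len(min(nrow(cand), 6L))) {
      eid <- cand[k, "eid"]; vx <- cand[k, "vertex"]
      tgt <- truth$paths[[eid]][vx, ]
      t <- seq(0, 1, length.out = max(3L, ceiling(cand[k, "d"])))
      conn <- cbind(p0[1] + t * (tgt[1] - p0[1]), p0[2] + t * (tgt[2] - p0[2]))
      clash <- FALSE
      for (ei in seq_along(truth$paths)) {
        if (ei %in% c(inc, eid)) next
        path <- truth$paths[[ei]]
        clear <- (truth$edges$caliber_px[ei] + truth$edges$caliber_px[inc[1]]) / 2 + 2
        dmin <- min(outer(conn[, 1], path[, 1], `-`)^2 +
                    outer(conn[, 2], path[, 2], `-`)^2)
        if (dmin < clear^2) { clash <- TRUE; break }
      }
      if (!clash) {
        truth <- splice_edge(truth, ep, eid, vx)
        break
      }
    }
  }
  truth
}

node_degrees <- function(truth) {
  tabulate(c(truth$edges$from, truth$edges$to), nbins = nrow(truth$nodes))
}

# Split edge `eid` at path vertex `vertex`, add a node there, and connect the
# endpoint node `ep` to it with a gently bowed 3-point polyline.
splice_edge <- function(truth, ep, eid, vertex) {
  path <- truth$paths[[eid]]
  e <- truth$edges[eid, ]
  newn <- nrow(truth$nodes) + 1L
  truth$nodes <- rbind(truth$nodes,
                       data.frame(id = newn, x = path[vertex, 1], y = path[vertex, 2]))
  # split target edge
  nid <- nrow(truth$edges) + 1L
  truth$edges$to[eid] <- newn
  truth$paths[[eid]] <- path[1:vertex, , drop = FALSE]
  truth$edges <- rbind(truth$edges,
    data.frame(id = nid, from = newn, to = e$to, caliber_px = e$caliber_px,
               depth = e$depth))
  truth$paths[[nid]] <- path[vertex:nrow(path), , drop = FALSE]
  # connector from the endpoint to the new node
  p0 <- c(truth$nodes$x[ep], truth$nodes$y[ep])
  p1 <- c(path[vertex, 1], path[vertex, 2])
  mid <- (p0 + p1) / 2 + rnorm(2, 0, 1.5)
  cid <- nrow(truth$edges) + 1L
  inc <- truth$edges$caliber_px[truth$edges$from == ep | truth$edges$to == ep]
  truth$edges <- rbind(truth$edges,
    data.frame(id = cid, from = ep, to = newn,
               caliber_px = max(truth$params$caliber_min_px,
                                0.9 * min(c(inc, e$caliber_px))),
               depth = max(truth$edges$depth) ))
  truth$paths[[cid]] <- rbind(p0, mid, p1)
  truth
}

polyline_length <- function(xy) sum(sqrt(rowSums(diff(xy)^2)))

# Convex lesion hull around all centerline points, slightly dilated so every
# tube lies strictly inside.
lesion_hull <- function(truth, margin_px = NULL) {
  pts <- do.call(rbind, truth$paths)
  if (is.null(pts) || nrow(pts) < 3L) return(NULL)
  margin_px <- margin_px %||% (max(truth$edges$caliber_px) / 2 + 3)
  h <- chull(pts)
  v <- pts[h, , drop = FALSE]
  ctr <- colMeans(v)
  v <- sweep(sweep(v, 2, ctr), 1,
             1 + margin_px / pmax(sqrt(rowSums(sweep(v, 2, ctr)^2)), 1e-9), `*`)
  v <- sweep(v, 2, ctr, `+`)
  v[, 1] <- pmin(pmax(v[, 1], 0), truth$shape[2])
  v[, 2] <- pmin(pmax(v[, 2], 0), truth$shape[1])
  colnames(v) <- c("x", "y")
  v
}

# Rasterize the tube union (and the 1-px centerlines) of a network.
rasterize_tubes <- function(truth, shape = truth$shape) {
  h <- shape[1]; w <- shape[2]
  tube <- matrix(FALSE, h, w)
  center <- matrix(FALSE, h, w)
  for (i in seq_along(truth$paths)) {
    path <- truth$paths[[i]]
    rad <- truth$edges$caliber_px[i] / 2
    # dense samples every ~0.5 px along the polyline
    seg <- diff(path)
    lens <- sqrt(rowSums(seg^2))
    samp <- list(path[1, , drop = FALSE])
    for (k in seq_len(nrow(seg))) {
      if (lens[k] == 0) next
      t <- seq(0, 1, length.out = max(2L, ceiling(lens[k] / 0.5) + 1L))
      samp[[k + 1L]] <- cbind(path[k, 1] + t * seg[k, 1], path[k, 2] + t * seg[k, 2])
    }
    pts <- do.call(rbind, samp)
    cc <- floor(pts[, 1]) + 1L
    rr <- floor(pts[, 2]) + 1L
    okc <- cc >= 1L & cc <= w & rr >= 1L & rr <= h
    center[cbind(rr[okc], cc[okc])] <- TRUE
    # stamp discs of radius rad around each sample (pixel centers at -0.5)
    ir <- ceiling(rad + 0.5)
    offs <- expand.grid(dr = -ir:ir, dc = -ir:ir)
    for (oi in seq_len(nrow(offs))) {
      r2 <- rr + offs$dr[oi]; c2 <- cc + offs$dc[oi]
      ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
      if (!any(ok)) next
      dx <- (c2[ok] - 0.5) - pts[ok, 1]
      dy <- (r2[ok] - 0.5) - pts[ok, 2]
      hit <- dx^2 + dy^2 <= rad^2
      if (any(hit)) tube[cbind(r2[ok][hit], c2[ok][hit])] <- TRUE
    }
  }
  list(tube = tube, centerline = center)
}

# Fill lesion polygon, true metrics, and return the completed truth object.
finalize_truth <- function(truth) {
  truth$lesion_polygon <- lesion_hull(truth)
  scale <- truth$pixel_scale_mm
  if (nrow(truth$edges) == 0L || is.null(truth$lesion_polygon)) {
    tm <- list(mcnv_area_mm2 = 0, vessel_area_mm2 = 0, vessel_density = NA_real_,
               vessel_length_mm = 0, vessel_diameter_um = NA_real_,
               fractal_dimension = NA_real_, vessel_junctions = 0L,
               junction_density_per_mm = NA_real_, vessel_tortuosity = NA_real_,
               crt_um = NA_real_)
    class(tm) <- "biomarker_panel"
    truth$true_metrics <- tm
    return(truth)
  }
  arcs <- vapply(truth$paths, polyline_length, numeric(1))
  chords <- vapply(truth$paths, function(p)
    sqrt(sum((p[1, ] - p[nrow(p), ])^2)), numeric(1))
  vl <- sum(arcs) * scale
  vj <- sum(node_degrees(truth) >= 3L)
  ras <- rasterize_tubes(truth)
  lesion <- rasterize_contour(truth$lesion_polygon, truth$shape, scale)
  va <- sum(ras$tube) * scale^2
  mcnv <- sum(lesion$mask) * scale^2
  ok <- chords > 1e-9
  tm <- list(
    mcnv_area_mm2 = mcnv, vessel_area_mm2 = va,
    vessel_density = if (mcnv > 0) va / mcnv else NA_real_,
    vessel_length_mm = vl,
    vessel_diameter_um = if (vl > 0) 1000 * va / vl else NA_real_,
    # ground truth uses the offset-averaged estimator: lower variance on
    # small point sets, so treatment-induced complexity changes are not
    # swamped by grid-anchoring noise
    fractal_dimension = tryCatch(fractal_dimension(ras$centerline, offsets = 4),
                                 octamorph_error = function(e) NA_real_),
    vessel_junctions = vj,
    junction_density_per_mm = if (vl > 0) vj / vl else NA_real_,
    vessel_tortuosity = if (any(ok)) mean(arcs[ok] / chords[ok]) else NA_real_,
    crt_um = NA_real_)
  class(tm) <- "biomarker_panel"
  truth$true_metrics <- tm
  truth
}

#' @export
print.vessel_network_truth <- function(x, ...) {
  cat(sprintf("<vessel_network_truth> pattern=%s seed=%d: %d edges, %d junctions, VL=%.3f mm\n",
              x$pattern, x$seed, nrow(x$edges),
              x$true_metrics$vessel_junctions, x$true_metrics$vessel_length_mm))
  invisible(x)
}

#' Simulated anti-VEGF treatment effect
#'
#' Removes every centerline segment with caliber below `prune_caliber_px`
#' (small new vessels regress first) together with any part of the network
#' that becomes disconnected from its roots, dilates the surviving calibers
#' by `trunk_dilation` (surviving trunks carry more flow), shrinks the lesion
#' hull to the survivors, and recomputes the ground-truth metrics. Pruning
#' everything yields a legal empty network with zeroed metrics — the fully
#' regressed case.
#'
#' @param truth A [generate_network()] result.
#' @param prune_caliber_px Caliber threshold in px; segments thinner than this
#'   are removed.
#' @param trunk_dilation Multiplier (`>= 1`) applied to surviving calibers.
#' @param seed Accepted for interface symmetry; the transform itself is
#'   deterministic.
#' @return A new `vessel_network_truth`.
#' @export
apply_anti_vegf <- function(truth, prune_caliber_px, trunk_dilation = 1.15,
                            seed = NULL) {
  if (!inherits(truth, "vessel_network_truth"))
    stop_validation("`truth` must be a vessel_network_truth")
  if (!is_scalar_number(trunk_dilation) || trunk_dilation < 1)
    stop_validation("`trunk_dilation` must be >= 1")
  keep <- truth$edges$caliber_px >= prune_caliber_px
  # orphan removal: only parts still connected to a root survive
  if (any(keep)) {
    g <- igraph::make_empty_graph(n = nrow(truth$nodes), directed = FALSE)
    g <- igraph::add_edges(g, rbind(truth$edges$from[keep], truth$edges$to[keep]))
    comp <- igraph::components(g)$membership
    rooted <- comp[truth$edges$from] %in% unique(comp[truth$roots])
    keep <- keep & rooted
  }
  out <- truth
  out$edges <- truth$edges[keep, , drop = FALSE]
  out$paths <- truth$paths[keep]
  if (nrow(out$edges)) {
    out$edges$caliber_px <- out$edges$caliber_px * trunk_dilation
    out$edges$id <- seq_len(nrow(out$edges))
  }
  finalize_truth(out)
}

#' Render a synthetic network as an OCTA-like en face image
#'
#' Rasterizes each centerline as a tube of its caliber at full intensity,
#' adds a background level, multiplies by lognormal speckle (unit mean), and
#' blurs with a Gaussian — a first-order emulation of OCTA flow-signal
#' appearance. The lesion mask comes from the ground-truth hull polygon.
#'
#' @param truth A `vessel_network_truth` with at least one edge.
#' @param noise List with `speckle_sigma` (lognormal sigma; 0 = none),
#'   `background_level` (additive floor in `[0, 1)`), `blur_px` (Gaussian
#'   sigma; 0 = none).
#' @param seed RNG seed for the speckle field.
#' @param shape Output image shape.
#' @return List with `image` ([enface_image]), `mask` ([lesion_mask]) and
#'   `truth`.
#' @export
render_octa <- function(truth, noise = list(speckle_sigma = 0.3,
                                            background_level = 0.12,
                                            blur_px = 0.8),
                        seed = 1, shape = truth$shape) {
  if (!inherits(truth, "vessel_network_truth"))
    stop_validation("`truth` must be a vessel_network_truth")
  if (is.null(truth$lesion_polygon))
    stop_validation("cannot render an empty network")
  speckle <- noise$speckle_sigma %||% 0
  bg <- noise$background_level %||% 0
  blur <- noise$blur_px %||% 0
  ras <- rasterize_tubes(truth, shape)
  img <- bg + (1 - bg) * ras$tube
  if (speckle > 0) {
    img <- with_seed(seed,
      img * matrix(rlnorm(length(img), -speckle^2 / 2, speckle), nrow(img)))
    img <- pmin(img, quantile(img, 0.999))   # tame extreme speckle tail
  }
  ei <- enface_image(img / max(img), pixel_scale_mm = truth$pixel_scale_mm,
                     normalize = FALSE)
  if (blur > 0) ei <- gaussian_denoise(ei, blur)
  ei <- enface_image(ei$pixels, pixel_scale_mm = truth$pixel_scale_mm)
  mask <- rasterize_contour(truth$lesion_polygon, shape, truth$pixel_scale_mm)
  list(image = ei, mask = mask, truth = truth)
}

#' Simulate a treated mCNV cohort with ground-truth panels
#'
#' Generates `n_eyes` networks with the clinical phenotype mix (medusa,
#' sea-fan and tree-in-bud interlacing subtypes, plus disorganized loops),
#' applies the anti-VEGF pruning transform to each, and returns ground-truth
#' biomarker panels at both timepoints together with qualitative metadata.
#' CRT values are drawn to co-vary loosely with the lesion-area response so
#' that the percent-change correlation analysis has signal to find.
#'
#' @param n_eyes Number of eyes.
#' @param seed RNG seed.
#' @param prune_quantile Caliber quantile at which each network is pruned.
#' @param trunk_dilation Caliber multiplier for survivors.
#' @return List with `baseline` and `post` panel data.frames (conventional
#'   columns plus `CRT`), and `meta` (`pattern, OP, n_injections`).
#' @export
simulate_cohort <- function(n_eyes = 31, seed = 1, prune_quantile = 0.55,
                            trunk_dilation = 1.15) {
  with_seed(seed, {
    pats <- sample(c("medusa", "sea_fan", "tree_in_bud", "disorganized_loops"),
                   n_eyes, replace = TRUE,
                   prob = c(12, 3, 11, 5) / 31)
    seeds <- sample.int(1e6, n_eyes)
    base_rows <- post_rows <- vector("list", n_eyes)
    meta <- data.frame(pattern = pats,
                       OP = ifelse(pats == "disorganized_loops", "DVL", "OI"),
                       n_injections = sample(1:4, n_eyes, replace = TRUE,
                                             prob = c(0.25, 0.4, 0.25, 0.1)))
    for (i in seq_len(n_eyes)) {
      tr <- generate_network(pats[i], seed = seeds[i])
      q <- quantile(tr$edges$caliber_px, prune_quantile, names = FALSE)
      post <- apply_anti_vegf(tr, prune_caliber_px = q,
                              trunk_dilation = trunk_dilation)
      b <- as.data.frame(tr$true_metrics)
      p <- as.data.frame(post$true_metrics)
      b$CRT <- rnorm(1, 316, 70)
      pc_area <- if (b$mCNV_area > 0) 100 * (p$mCNV_area - b$mCNV_area) / b$mCNV_area else -50
      pc_crt <- pmax(-60, 0.3 * pc_area - 12 + rnorm(1, 0, 8))
      p$CRT <- b$CRT * (1 + pc_crt / 100)
      base_rows[[i]] <- b
      post_rows[[i]] <- p
    }
    list(baseline = do.call(rbind, base_rows),
         post = do.call(rbind, post_rows), meta = meta)
  })
}
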