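# Shift a matrix by (dr, dc), filling vacated cells with FALSE/0.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs + dr, cs + dc] <- m[rs, cs]
  out
}

# The 8 neighbors of every pixel in Zhang-Suen order P2..P9
# (N, NE, E, SE, S, SW, W, NW), as a list of logical matrices.
neighbor_stack <- function(m) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  lapply(offs, function(o) shift_mat(m, -o[1], -o[2]))
}

#' Skeletonize a binary vessel map (Zhang-Suen thinning)
#'
#' Iterative two-subcycle thinning on 8-connectivity, run to its fixed point.
#' The result is a deterministic, 1-pixel-wide, topology-preserving
#' approximation of the medial axis; a second application changes nothing.
#'
#' @param binary A `binary_vessel_map` or logical matrix.
#' @return An object of class `skeleton_map`: list with `mask` (logical),
#'   `parent` (the input mask) and `pixel_scale_mm`.
#' @export
skeletonize <- function(binary) {
  m <- if (inherits(binary, "binary_vessel_map")) binary$mask else binary != 0
  scale <- if (inherits(binary, "binary_vessel_map")) binary$pixel_scale_mm
           else DEFAULT_PIXEL_SCALE_MM
  if (!is.matrix(m)) stop_validation("`binary` must be a matrix or binary_vessel_map")
  sk <- m
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- neighbor_stack(sk)
      b <- Reduce(`+`, nb)
      # A = number of 0->1 transitions in the cyclic sequence P2..P9 P2
      a <- matrix(0L, nrow(sk), ncol(sk))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        a <- a + (!nb[[i]] & nb[[j]])
      }
      if (sub == 1) {
        cond <- sk & b >= 2 & b <= 6 & a == 1 &
          !(nb[[1]] & nb[[3]] & nb[[5]]) & !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cond <- sk & b >= 2 & b <= 6 & a == 1 &
          !(nb[[1]] & nb[[3]] & nb[[7]]) & !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      if (any(cond)) {
        sk[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sk <- minimize_skeleton(sk)
  structure(list(mask = sk, parent = m, pixel_scale_mm = scale),
            class = "skeleton_map")
}

# Remove redundant pixels left by parallel thinning (2-px staircase
# remnants whose diagonal shortcuts masquerade as degree-3 pixels). A pixel
# is redundant when its foreground neighbors form a single mutually
# 8-connected set without it: deleting it then neither changes connectivity
# nor shortens a branch end, which is exactly the thinning fixed point the
# skeleton is required to reach. Deletion is sequential, so adjacent
# redundant pixels cannot break a chain.
minimize_skeleton <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  offs <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                dc = c(0, 1, 1, 1, 0, -1, -1, -1))
  repeat {
    removed <- FALSE
    for (p in which(sk)) {
      if (!sk[p]) next
      r <- (p - 1L) %% nr + 1L
      cc <- (p - 1L) %/% nr + 1L
      rs <- r + offs[, 1]; cs <- cc + offs[, 2]
      ok <- rs >= 1L & rs <= nr & cs >= 1L & cs <= nc
      nb <- which(ok)[sk[cbind(rs[ok], cs[ok])]]
      k <- length(nb)
      if (k < 2L) next
      # connectivity of the neighbor set among themselves (chebyshev <= 1)
      pr <- rs[nb]; pc <- cs[nb]
      adj <- outer(pr, pr, function(a, b) abs(a - b)) <= 1L &
             outer(pc, pc, function(a, b) abs(a - b)) <= 1L
      seen <- logical(k); seen[1] <- TRUE
      repeat {
        grow <- seen | (colSums(adj & seen) > 0L)
        if (all(grow == seen)) break
        seen <- grow
      }
      if (all(seen)) {
        sk[p] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %d skeleton px, total length %.4f mm\n",
              sum(x$mask), total_length_mm(x)))
  invisible(x)
}

#' Total skeleton length
#'
#' Sum over all pairs of 8-adjacent skeleton pixels, each adjacency counted
#' once: orthogonal steps contribute 1 px, diagonal steps `sqrt(2)` px, then
#' converted to mm by the pixel scale.
#'
#' @param skel A `skeleton_map` or logical matrix.
#' @param pixel_scale_mm Override the pixel scale (required when `skel` is a
#'   bare matrix).
#' @return Length in mm (0 for an empty skeleton).
#' @export
total_length_mm <- function(skel, pixel_scale_mm = NULL) {
  m <- if (inherits(skel, "skeleton_map")) skel$mask else skel != 0
  scale <- pixel_scale_mm %||%
    (if (inherits(skel, "skeleton_map")) skel$pixel_scale_mm else DEFAULT_PIXEL_SCALE_MM)
  pr <- adjacent_pairs8(m)
  if (!nrow(pr)) return(0)
  nr <- nrow(m)
  dr <- abs((pr[, 1] - 1L) %% nr - (pr[, 2] - 1L) %% nr)
  dc <- abs((pr[, 1] - 1L) %/% nr - (pr[, 2] - 1L) %/% nr)
  sum(ifelse(dr + dc == 2L, sqrt(2), 1)) * scale
}
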