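# Core skeleton-graph machinery: classify skeleton pixels by 8-neighbor
# count (1 = endpoint, 2 = branch interior, >=3 = junction pixel), merge
# 8-adjacent junction pixels into junction clusters, and partition every
# skeleton adjacency into branch paths (each adjacency belongs to exactly one
# traced path, so lengths account exactly).

# Trace one pass over a skeleton mask. Returns the raw decomposition.
trace_skeleton <- function(sk) {
  nr <- nrow(sk)
  idx <- which(sk)
  n <- length(idx)
  pos <- integer(length(sk)); pos[idx] <- seq_len(n)
  pr <- adjacent_pairs8(sk)           # each adjacency once, linear indices
  m_edges <- nrow(pr)
  # adjacency list in compact-position space
  a <- pos[pr[, 1]]; b <- pos[pr[, 2]]
  deg <- tabulate(c(a, b), nbins = n)
  inc <- vector("list", n)            # incident edge ids per pixel
  if (m_edges) {
    eid <- seq_len(m_edges)
    inc_split <- split(c(eid, eid), c(a, b))
    inc[as.integer(names(inc_split))] <- inc_split
  }
  other_end <- function(e, v) if (a[e] == v) b[e] else a[e]

  is_junction <- deg >= 3L
  # junction clusters: components of the junction-pixel subgraph
  jcluster <- integer(n)              # 0 = not a junction pixel
  if (any(is_junction)) {
    jpos <- which(is_junction)
    jmap <- integer(n); jmap[jpos] <- seq_along(jpos)
    keep <- is_junction[a] & is_junction[b]
    g <- igraph::make_empty_graph(n = length(jpos), directed = FALSE)
    if (any(keep)) g <- igraph::add_edges(g, rbind(jmap[a[keep]], jmap[b[keep]]))
    jcluster[jpos] <- igraph::components(g)$membership
  }

  terminal <- deg != 2L | is_junction
  visited <- logical(m_edges)
  branches <- list()
  walk <- function(v0, e0) {
    path <- v0
    v <- v0; e <- e0
    repeat {
      visited[e] <<- TRUE
      v <- other_end(e, v)
      path <- c(path, v)
      if (terminal[v]) break
      nxt <- inc[[v]][!visited[inc[[v]]]]
      if (!length(nxt)) break        # closed a pure cycle back into itself
      e <- nxt[1]
    }
    path
  }
  for (v0 in which(terminal & deg > 0L)) {
    for (e0 in inc[[v0]]) {
      if (!visited[e0]) branches[[length(branches) + 1L]] <- walk(v0, e0)
    }
  }
  # leftover edges are pure deg-2 cycles
  cycle_flag <- rep(FALSE, length(branches))
  while (any(!visited)) {
    e0 <- which(!visited)[1]
    p <- walk(a[e0], e0)
    branches[[length(branches) + 1L]] <- p
    cycle_flag[length(branches)] <- TRUE
  }
  list(idx = idx, pos = pos, nr = nr, deg = deg, is_junction = is_junction,
       jcluster = jcluster, branches = branches, cycle_flag = cycle_flag)
}

path_coords <- function(p, tr) {
  lin <- tr$idx[p]
  cbind(row = (lin - 1L) %% tr$nr + 1L, col = (lin - 1L) %/% tr$nr + 1L)
}

step_sum_px <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  d <- abs(diff(xy))
  sum(ifelse(rowSums(d) == 2L, sqrt(2), 1))
}

#' Decompose a skeleton into junctions, endpoints and branches
#'
#' Each skeleton pixel is classified by its 8-neighbor count (1 = endpoint,
#' 2 = branch interior, >= 3 = junction pixel); 8-adjacent junction pixels are
#' merged into a single junction cluster, so a 4-valent crossing counts as one
#' junction. Branches are traced between terminals (junction clusters or
#' endpoints); pure cycles are allowed and flagged. Thinning spurs - endpoint
#' branches not longer than `prune_px` - are deleted (iteratively) before the
#' final decomposition.
#'
#' @param skel A `skeleton_map` (or logical matrix).
#' @param prune_px Spur-pruning threshold in px (0 disables). A branch is a
#'   spur if one end is an endpoint and its step-sum length is `<= prune_px`.
#' @param merge_junction_px Contract junction-to-junction bridges whose
#'   step-sum length is `<= merge_junction_px` into a single junction
#'   (0 disables). Parallel thinning can split one anatomical bifurcation
#'   into two triple points a few pixels apart; this is the internal
#'   counterpart of spur pruning. The contracted bridge length is accounted
#'   under `internal_length_mm`.
#' @param pixel_scale_mm Override pixel scale for bare matrices.
#' @return An object of class `skeleton_graph`: list with
#'   \describe{
#'   \item{junctions}{data.frame `id, n_px, row, col` (cluster centroids)}
#'   \item{endpoints}{data.frame `row, col`}
#'   \item{branches}{data.frame `id, from, to, n_px, path_length_px,
#'     path_length_mm, chord_px, chord_length_mm, is_cycle`}
#'   \item{paths}{list of branch pixel paths (matrices `row, col`)}
#'   \item{internal_length_mm}{length of adjacencies inside multi-pixel
#'     junction clusters (kept separate from branches)}
#'   \item{n_isolated}{isolated skeleton pixels}
#'   \item{mask}{the (pruned) skeleton mask}
#'   }
#' @export
build_graph <- function(skel, prune_px = 3, merge_junction_px = 5,
                        pixel_scale_mm = NULL) {
  sk <- if (inherits(skel, "skeleton_map")) skel$mask else skel != 0
  scale <- pixel_scale_mm %||%
    (if (inherits(skel, "skeleton_map")) skel$pixel_scale_mm else DEFAULT_PIXEL_SCALE_MM)

  # Iterative spur pruning. A spur is an endpoint-terminated branch not
  # longer than prune_px hanging off a junction cluster. Pruning must not
  # demote a real junction: when the cluster has only three connections the
  # spur is removed only if a second short endpoint arm shows the cluster to
  # be a tip-fork artifact (two prongs at a branch end) rather than an
  # anatomical bifurcation with a parasitic stub.
  repeat {
    tr <- trace_skeleton(sk)
    if (prune_px <= 0 || !length(tr$branches)) break
    lens <- vapply(seq_along(tr$branches), function(i)
      step_sum_px(path_coords(tr$branches[[i]], tr)), numeric(1))
    ends <- lapply(tr$branches, function(p) c(p[1], p[length(p)]))
    cluster_of <- function(v) if (tr$is_junction[v]) tr$jcluster[v] else 0L
    end_clusters <- lapply(ends, function(e) c(cluster_of(e[1]), cluster_of(e[2])))
    is_endpoint_branch <- vapply(ends, function(e)
      tr$deg[e[1]] == 1L || tr$deg[e[2]] == 1L, logical(1))
    removed <- FALSE
    for (i in seq_along(tr$branches)) {
      if (tr$cycle_flag[i]) next
      e <- ends[[i]]
      free1 <- tr$deg[e[1]] <= 1L; free2 <- tr$deg[e[2]] <= 1L
      if (free1 == free2) next          # keep isolated segments; skip J-J bars
      if (lens[i] > prune_px) next
      jcl <- max(end_clusters[[i]])
      if (jcl > 0L) {
        inc <- setdiff(which(vapply(end_clusters, function(ec) jcl %in% ec,
                                    logical(1))), i)
        tip_fork <- any(is_endpoint_branch[inc] & lens[inc] <= 2 * prune_px)
        if (length(inc) < 3L && !tip_fork) next
      }
      p <- tr$branches[[i]]
      drop <- p[!tr$is_junction[p]]
      sk[tr$idx[drop]] <- FALSE
      removed <- TRUE
    }
    if (!removed) break
  }

  tr <- trace_skeleton(sk)
  n <- length(tr$idx)
  rc <- cbind((tr$idx - 1L) %% tr$nr + 1L, (tr$idx - 1L) %/% tr$nr + 1L)

  # junction clusters
  ncl <- max(tr$jcluster, 0L)
  junctions <- if (ncl > 0L) {
    do.call(rbind, lapply(seq_len(ncl), function(k) {
      px <- which(tr$jcluster == k)
      data.frame(id = k, n_px = length(px),
                 row = mean(rc[px, 1]), col = mean(rc[px, 2]))
    }))
  } else data.frame(id = integer(), n_px = integer(), row = numeric(), col = numeric())

  ep <- which(tr$deg == 1L)
  endpoints <- data.frame(row = rc[ep, 1], col = rc[ep, 2])

  node_label <- function(v) {
    if (tr$is_junction[v]) paste0("J", tr$jcluster[v])
    else if (tr$deg[v] == 1L) paste0("E", match(v, ep))
    else paste0("C", v)   # cycle anchor (interior pixel)
  }

  paths <- list(); rows <- list(); internal_px <- 0
  bid <- 0L
  for (i in seq_along(tr$branches)) {
    p <- tr$branches[[i]]
    xy <- path_coords(p, tr)
    len <- step_sum_px(xy)
    if (all(tr$is_junction[p])) {     # connector inside a junction cluster
      internal_px <- internal_px + len
      next
    }
    is_cyc <- tr$cycle_flag[i]
    chord <- if (is_cyc) max_pairwise_dist(xy)
             else sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2))
    if (!is_cyc && chord == 0 && nrow(xy) > 1L)  # lasso loop anchored at one node
      chord <- max_pairwise_dist(xy)
    bid <- bid + 1L
    paths[[bid]] <- xy
    rows[[bid]] <- data.frame(
      id = bid, from = node_label(p[1]), to = node_label(p[length(p)]),
      n_px = nrow(xy), path_length_px = len, path_length_mm = len * scale,
      chord_px = chord, chord_length_mm = chord * scale, is_cycle = is_cyc)
  }
  branches <- if (bid) do.call(rbind, rows)
    else data.frame(id = integer(), from = character(), to = character(),
                    n_px = integer(), path_length_px = numeric(),
                    path_length_mm = numeric(), chord_px = numeric(),
                    chord_length_mm = numeric(), is_cycle = logical())

  # contract short junction-junction bridges (split triple points)
  if (merge_junction_px > 0 && nrow(junctions) > 1L && nrow(branches)) {
    jf <- grepl("^J", branches$from) & grepl("^J", branches$to)
    bridge <- which(jf & branches$from != branches$to & !branches$is_cycle &
                    branches$path_length_px <= merge_junction_px)
    if (length(bridge)) {
      g <- igraph::make_empty_graph(n = nrow(junctions), directed = FALSE)
      g <- igraph::add_edges(g, rbind(
        as.integer(sub("^J", "", branches$from[bridge])),
        as.integer(sub("^J", "", branches$to[bridge]))))
      grp <- igraph::components(g)$membership
      junctions$group <- grp[junctions$id]
      merged <- do.call(rbind, lapply(split(junctions, junctions$group), function(d)
        data.frame(id = d$group[1], n_px = sum(d$n_px),
                   row = sum(d$row * d$n_px) / sum(d$n_px),
                   col = sum(d$col * d$n_px) / sum(d$n_px))))
      remap <- setNames(paste0("J", grp), paste0("J", seq_along(grp)))
      internal_px <- internal_px + sum(branches$path_length_px[bridge])
      keep <- setdiff(seq_len(nrow(branches)), bridge)
      branches <- branches[keep, , drop = FALSE]
      paths <- paths[keep]
      if (nrow(branches)) {
        branches$id <- seq_len(nrow(branches))
        jb <- grepl("^J", branches$from)
        branches$from[jb] <- remap[branches$from[jb]]
        jb <- grepl("^J", branches$to)
        branches$to[jb] <- remap[branches$to[jb]]
      }
      merged$id <- seq_len(nrow(merged))  # ids are arbitrary labels
      junctions <- merged
    }
  }

  structure(list(junctions = junctions, endpoints = endpoints,
                 branches = branches, paths = paths,
                 internal_length_mm = internal_px * scale,
                 n_isolated = sum(tr$deg == 0L),
                 mask = sk, pixel_scale_mm = scale, prune_px = prune_px),
            class = "skeleton_graph")
}

max_pairwise_dist <- function(xy) {
  if (nrow(xy) < 2L) return(0)
  # loops are short; the O(n^2) diameter is fine and exact
  d <- as.matrix(stats::dist(xy))
  max(d)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d junctions, %d endpoints, %d branches (%d cycles), %.4f mm\n",
              nrow(x$junctions), nrow(x$endpoints), nrow(x$branches),
              sum(x$branches$is_cycle), sum(x$branches$path_length_mm) + x$internal_length_mm))
  invisible(x)
}

#' Number of vessel junctions
#'
#' @param graph A [build_graph()] result.
#' @param count `"clusters"` (default) counts merged junction clusters, so a
#'   4-valent crossing is one junction; `"pixels"` counts raw skeleton pixels
#'   with >= 3 neighbors (sensitivity-analysis convention).
#' @return Non-negative integer.
#' @export
junction_count <- function(graph, count = c("clusters", "pixels")) {
  count <- match.arg(count)
  if (!inherits(graph, "skeleton_graph")) stop_validation("`graph` must be a skeleton_graph")
  if (count == "clusters") nrow(graph$junctions) else sum(graph$junctions$n_px)
}

#' Export a skeleton graph as CSV tables
#'
#' Writes `nodes.csv` (`id, type, x, y`; junction centroids and endpoints) and
#' `branches.csv` (`id, node_a, node_b, path_length_mm, chord_length_mm,
#' is_cycle`).
#'
#' @param graph A `skeleton_graph`.
#' @param dir Output directory (created if missing).
#' @return The two file paths, invisibly.
#' @export
write_graph_csv <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nodes <- rbind(
    if (nrow(graph$junctions))
      data.frame(id = paste0("J", graph$junctions$id), type = "junction",
                 x = graph$junctions$col, y = graph$junctions$row),
    if (nrow(graph$endpoints))
      data.frame(id = paste0("E", seq_len(nrow(graph$endpoints))), type = "endpoint",
                 x = graph$endpoints$col, y = graph$endpoints$row)
  )
  if (is.null(nodes)) nodes <- data.frame(id = character(), type = character(),
                                          x = numeric(), y = numeric())
  f1 <- file.path(dir, "nodes.csv")
  f2 <- file.path(dir, "branches.csv")
  write.csv(nodes, f1, row.names = FALSE)
  br <- graph$branches[, c("id", "from", "to", "path_length_mm",
                           "chord_length_mm", "is_cycle")]
  names(br)[2:3] <- c("node_a", "node_b")
  write.csv(br, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
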