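# Tree-structured analysis of contracting regions across time: small early
# regions (leaves = contraction origins) link forward to the merged
# peak-contraction region (root); parenthood = centroid containment.

#' Label contracting regions of one frame
#'
#' 8-connected components of the grid contraction mask; components smaller
#' than `min_area_um2` are dropped. Centroids are the unweighted means of
#' member grid-cell positions, reported in um.
#'
#' @param mask logical matrix on the vector grid.
#' @param grid_x,grid_y grid center coordinates (px).
#' @param pixel_size_um microns per px.
#' @param min_area_um2 minimum region area retained.
#' @param block_area_um2 area of one grid cell.
#' @return list of regions: each `list(cells, area_um2, centroid_um)` where
#'   `cells` are linear indices into the mask matrix.
#' @export
label_regions <- function(mask, grid_x, grid_y, pixel_size_um = 0.9616,
                          min_area_um2 = 4840, block_area_um2 = 532.6) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  nlab <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    labels[start] <- nlab
    while (length(queue)) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (cell - 1L) %% ny + 1L
      j <- (cell - 1L) %/% ny + 1L
      for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > ny || jj < 1L || jj > nx) next
        nb <- (jj - 1L) * ny + ii
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- nlab
          queue <- c(queue, nb)
        }
      }
    }
  }
  out <- list()
  for (l in seq_len(nlab)) {
    cells <- which(labels == l)
    area <- length(cells) * block_area_um2
    if (area < min_area_um2) next
    i <- (cells - 1L) %% ny + 1L
    j <- (cells - 1L) %/% ny + 1L
    out[[length(out) + 1L]] <- list(
      cells = cells, area_um2 = area,
      centroid_um = c(x = mean(grid_x[j]) * pixel_size_um,
                      y = mean(grid_y[i]) * pixel_size_um))
  }
  out
}

#' Segment a video into contraction cycles
#'
#' A cycle is a maximal run of frames with at least one retained contracting
#' region, bounded by rest (empty-mask) frames; a run touching the end of
#' the video is closed at the last frame. Alternatively (`method = "cv"`),
#' cycle boundaries are placed at local minima of a contraction-volume
#' series.
#'
#' @param active logical vector, one entry per frame (any region present).
#' @param method `"mask"` (default) or `"cv"`.
#' @param cv contraction-volume series, required for `method = "cv"`.
#' @return data.frame `cycle, start, end` (frame indices), zero rows if
#'   nothing is active.
#' @export
segment_cycles <- function(active, method = c("mask", "cv"), cv = NULL) {
  method <- match.arg(method)
  if (method == "cv") {
    if (is.null(cv)) stop_arg("method='cv' needs the cv series")
    n <- length(cv)
    lows <- which(vapply(seq_len(n), function(i) {
      l <- if (i > 1) cv[i - 1] else Inf
      r <- if (i < n) cv[i + 1] else Inf
      cv[i] <= l && cv[i] < r
    }, logical(1)))
    bounds <- unique(c(1L, lows, n))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    return(data.frame(cycle = seq_along(starts), start = starts, end = ends))
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0)
    return(data.frame(cycle = integer(), start = integer(), end = integer()))
  data.frame(cycle = seq_along(on), start = starts[on], end = ends[on])
}

# Build one cycle's tree from per-frame region lists.
# regions_by_frame: named by frame index (as character), each a list of
# regions as returned by label_regions. Returns node/edge data.frames plus
# member sets. Parenthood: processing nodes in ascending area, the parent of
# a node at frame t is the smallest-area region at the first later frame
# (searched frame-by-frame within the cycle) whose member set contains the
# node's centroid grid cell. Last-frame nodes and unattachable nodes are
# roots; depth runs root (0) downward.
build_tree <- function(regions_by_frame, frames, grid_x, grid_y,
                       pixel_size_um, cycle_id = 1L, id_offset = 0L) {
  nodes <- list()
  for (f in frames) {
    regs <- regions_by_frame[[as.character(f)]]
    if (is.null(regs)) next
    for (r in regs)
      nodes[[length(nodes) + 1L]] <- list(frame = f, region = r)
  }
  n <- length(nodes)
  if (n == 0)
    return(list(nodes = data.frame(), edges = data.frame(), members = list()))
  area <- vapply(nodes, function(nd) nd$region$area_um2, numeric(1))
  frame <- vapply(nodes, function(nd) nd$frame, numeric(1))
  ny <- length(grid_y)
  cell_of <- function(centroid_um) {
    j <- which.min(abs(grid_x * pixel_size_um - centroid_um["x"]))
    i <- which.min(abs(grid_y * pixel_size_um - centroid_um["y"]))
    (j - 1L) * ny + i
  }
  parent <- rep(NA_integer_, n)
  for (k in order(area)) {
    cand_frames <- frames[frames > frame[k]]
    cc <- cell_of(nodes[[k]]$region$centroid_um)
    for (f in cand_frames) {
      holders <- which(frame == f &
                         vapply(nodes, function(nd) cc %in% nd$region$cells,
                                logical(1)))
      if (length(holders)) {
        parent[k] <- holders[which.min(area[holders])]
        break
      }
    }
  }
  depth <- rep(NA_integer_, n)
  roots <- which(is.na(parent))
  depth[roots] <- 0L
  # lineage runs forward in time, so repeated sweeps terminate
  while (anyNA(depth)) {
    prog <- FALSE
    for (k in which(is.na(depth))) {
      if (!is.na(depth[parent[k]])) {
        depth[k] <- depth[parent[k]] + 1L
        prog <- TRUE
      }
    }
    if (!prog) stop("internal error: lineage cycle in tree construction")
  }
  id <- id_offset + seq_len(n)
  has_child <- seq_len(n) %in% parent[!is.na(parent)]
  nd <- data.frame(
    id = id, cycle = cycle_id, frame = frame, area_um2 = area,
    x_um = vapply(nodes, function(x) x$region$centroid_um[["x"]], numeric(1)),
    y_um = vapply(nodes, function(x) x$region$centroid_um[["y"]], numeric(1)),
    parent = ifelse(is.na(parent), NA_integer_, id_offset + parent),
    depth = depth,
    is_leaf = !has_child,
    is_root = is.na(parent))
  nd$is_singleton <- nd$is_leaf & nd$is_root
  edges <- data.frame(parent_id = nd$parent[!is.na(nd$parent)],
                      child_id = nd$id[!is.na(nd$parent)])
  members <- lapply(nodes, function(x) x$region$cells)
  names(members) <- as.character(id)
  list(nodes = nd, edges = edges, members = members)
}

#' Contraction forest of an AR-DIC fit
#'
#' Thresholds every frame's displacement field ([contraction_mask()]),
#' labels contracting regions ([label_regions()]), segments the video into
#' contraction cycles ([segment_cycles()]), and builds one region tree per
#' cycle. The result underlies origin detection ([find_origins()]), the
#' accumulated spatial contraction map ([asc_map()]) and the spatiotemporal
#' node/edge tables ([astc_table()]).
#'
#' @param fit an [ardic()] object.
#' @param criteria a [contraction_criteria()].
#' @param cycle_method passed to [segment_cycles()].
#' @return Object of class `contraction_forest`: `nodes`, `edges`,
#'   `members`, `cycles`, grid metadata.
#' @export
contraction_forest <- function(fit, criteria = contraction_criteria(),
                               cycle_method = "mask") {
  stopifnot(inherits(fit, "ardic"))
  fields <- Filter(Negate(is.null), fit$fields)
  f1 <- fields[[1]]
  regions <- list()
  active <- logical(length(fields))
  frame_ids <- integer(length(fields))
  cvs <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    mask <- contraction_mask(f, criteria$threshold_um)
    regs <- label_regions(mask, f$grid_x, f$grid_y, f$pixel_size_um,
                          criteria$min_region_area_um2, criteria$block_area_um2)
    frame_ids[i] <- f$frame_index
    regions[[as.character(f$frame_index)]] <- regs
    active[i] <- length(regs) > 0
    cvs[i] <- contraction_volume(f, mask, criteria$block_area_um2,
                                 criteria$norm_area_um2)
  }
  cycles <- segment_cycles(active, method = cycle_method, cv = cvs)
  # cycle start/end index into the measured-frame sequence
  all_nodes <- list(); all_edges <- list(); members <- list()
  off <- 0L
  for (ci in seq_len(nrow(cycles))) {
    fr <- frame_ids[cycles$start[ci]:cycles$end[ci]]
    tr <- build_tree(regions, fr, f1$grid_x, f1$grid_y, f1$pixel_size_um,
                     cycle_id = ci, id_offset = off)
    if (nrow(tr$nodes) == 0) next
    all_nodes[[length(all_nodes) + 1L]] <- tr$nodes
    all_edges[[length(all_edges) + 1L]] <- tr$edges
    members <- c(members, tr$members)
    off <- off + nrow(tr$nodes)
  }
  nodes <- if (length(all_nodes)) do.call(rbind, all_nodes) else data.frame()
  edges <- if (length(all_edges)) do.call(rbind, all_edges) else data.frame()
  structure(list(nodes = nodes, edges = edges, members = members,
                 cycles = cycles, grid_x = f1$grid_x, grid_y = f1$grid_y,
                 spacing_px = f1$spacing_px,
                 pixel_size_um = f1$pixel_size_um, fps = fit$fps),
            class = "contraction_forest")
}

#' @export
print.contraction_forest <- function(x, ...) {
  n <- nrow(x$nodes)
  cat(sprintf("contraction_forest: %d nodes in %d cycles\n", n, nrow(x$cycles)))
  if (n) {
    cat(sprintf("  %d roots, %d leaves, %d singletons; max depth %d\n",
                sum(x$nodes$is_root), sum(x$nodes$is_leaf),
                sum(x$nodes$is_singleton), max(x$nodes$depth)))
  }
  invisible(x)
}

# Subtree total area (um^2) per node, used to break origin-rank ties.
subtree_areas <- function(nodes) {
  total <- nodes$area_um2
  for (k in order(nodes$depth, decreasing = TRUE)) {
    p <- nodes$parent[k]
    if (!is.na(p)) {
      pi_ <- match(p, nodes$id)
      total[pi_] <- total[pi_] + total[k]
    }
  }
  total
}

#' Contraction origins from the forest
#'
#' Origins are the leaves of multi-node trees (a singleton is an independent
#' region, not an origin), ranked by depth below the root -- the deeper the
#' lineage, the earlier and stronger the origin -- with ties broken by
#' subtree total area. With `aggregate = TRUE` (default), per-cycle leaves
#' are clustered by centroid proximity so each physical origin appears once
#' across cycles, ranked by its deepest appearance.
#'
#' @param forest a [contraction_forest()].
#' @param aggregate cluster leaves across cycles.
#' @param cluster_radius_um centroid distance defining "the same origin"
#'   (default 1.5 grid spacings).
#' @return data.frame of origins, deepest first: `x_um, y_um, depth,
#'   subtree_area_um2, n_cycles, rank` (plus per-leaf rows when
#'   `aggregate = FALSE`).
#' @export
find_origins <- function(forest, aggregate = TRUE, cluster_radius_um = NULL) {
  nd <- forest$nodes
  empty <- data.frame(x_um = numeric(), y_um = numeric(), depth = integer(),
                      subtree_area_um2 = numeric(), n_cycles = integer(),
                      rank = integer())
  if (nrow(nd) == 0) return(empty)
  st <- subtree_areas(nd)
  leaves <- nd[nd$is_leaf & !nd$is_singleton, ]
  if (nrow(leaves) == 0) return(empty)
  leaves$subtree_area_um2 <- st[match(leaves$id, nd$id)]
  if (!aggregate) {
    leaves <- leaves[order(-leaves$depth, -leaves$subtree_area_um2), ]
    leaves$rank <- seq_len(nrow(leaves))
    return(leaves)
  }
  if (is.null(cluster_radius_um))
    cluster_radius_um <- 1.5 * forest$spacing_px * forest$pixel_size_um
  cl <- rep(NA_integer_, nrow(leaves))
  cx <- numeric(0); cy <- numeric(0)
  for (i in order(-leaves$depth, -leaves$subtree_area_um2)) {
    if (length(cx)) {
      dd <- sqrt((cx - leaves$x_um[i])^2 + (cy - leaves$y_um[i])^2)
      j <- which(dd <= cluster_radius_um)
      if (length(j)) { cl[i] <- j[1]; next }
    }
    cx <- c(cx, leaves$x_um[i]); cy <- c(cy, leaves$y_um[i])
    cl[i] <- length(cx)
  }
  agg <- do.call(rbind, lapply(seq_along(cx), function(j) {
    g <- leaves[cl == j, ]
    data.frame(x_um = mean(g$x_um), y_um = mean(g$y_um),
               depth = max(g$depth),
               subtree_area_um2 = max(g$subtree_area_um2),
               n_cycles = length(unique(g$cycle)))
  }))
  agg <- agg[order(-agg$depth, -agg$subtree_area_um2), ]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}

#' Accumulated spatial contraction (ASC) map
#'
#' Per grid point, the maximum tree depth over all nodes covering that
#' point, accumulated over every tree in the video (`accumulate = "sum"`
#' adds depths instead). Elevated peaks mark contraction origins and their
#' chain of influence.
#'
#' @param forest a [contraction_forest()].
#' @param accumulate `"max"` (default) or `"sum"` across nodes.
#' @return numeric matrix on the vector grid.
#' @export
asc_map <- function(forest, accumulate = c("max", "sum")) {
  accumulate <- match.arg(accumulate)
  ny <- length(forest$grid_y); nx <- length(forest$grid_x)
  m <- matrix(0, ny, nx)
  nd <- forest$nodes
  for (k in seq_len(nrow(nd))) {
    cells <- forest$members[[as.character(nd$id[k])]]
    if (accumulate == "max") {
      m[cells] <- pmax(m[cells], nd$depth[k])
    } else {
      m[cells] <- m[cells] + nd$depth[k]
    }
  }
  m
}

#' Accumulated spatiotemporal contraction (ASTC) tables
#'
#' Space-time node and edge tables of the contraction forest, suitable for
#' CSV export and 3-D plotting: each node carries its centroid (um), time
#' (s), area, tree depth, cycle, and origin/singleton flags; edges link
#' parent to child. Propagation delay between two origins in a cycle is the
#' difference of their leaf times.
#'
#' @param forest a [contraction_forest()].
#' @return `list(nodes, edges)` data.frames.
#' @export
astc_table <- function(forest) {
  nd <- forest$nodes
  if (nrow(nd) == 0)
    return(list(nodes = data.frame(), edges = data.frame()))
  nodes <- data.frame(id = nd$id, x_um = nd$x_um, y_um = nd$y_um,
                      t_s = (nd$frame - 1) / forest$fps,
                      area_um2 = nd$area_um2, depth = nd$depth,
                      cycle_id = nd$cycle,
                      is_origin = nd$is_leaf & !nd$is_singleton,
                      is_singleton = nd$is_singleton)
  list(nodes = nodes, edges = forest$edges)
}

#' Onset times of contraction origins per cycle
#'
#' For each cycle, the time (s) of every origin leaf, tagged with the
#' aggregated origin it belongs to (see [find_origins()]); differencing
#' onsets within a cycle gives the beat propagation delay between origins.
#'
#' @param forest a [contraction_forest()].
#' @return data.frame `cycle, origin_rank, onset_s`.
#' @export
origin_onsets <- function(forest) {
  origins <- find_origins(forest)
  leaves <- find_origins(forest, aggregate = FALSE)
  if (nrow(leaves) == 0)
    return(data.frame(cycle = integer(), origin_rank = integer(),
                      onset_s = numeric()))
  rad <- 1.5 * forest$spacing_px * forest$pixel_size_um
  rank_of <- vapply(seq_len(nrow(leaves)), function(i) {
    dd <- sqrt((origins$x_um - leaves$x_um[i])^2 +
               (origins$y_um - leaves$y_um[i])^2)
    j <- which.min(dd)
    if (dd[j] <= rad) origins$rank[j] else NA_integer_
  }, integer(1))
  out <- data.frame(cycle = leaves$cycle, origin_rank = rank_of,
                    onset_s = (leaves$frame - 1) / forest$fps)
  out[!is.na(out$origin_rank), ]
}
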