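# Region labeling, cycle segmentation, tree construction, origins, ASC/ASTC.

test_that("region labeling matches a graph-components oracle", {
  expect_length(label_regions(matrix(FALSE, 6, 6), 1:6 * 12, 1:6 * 12,
                              min_area_um2 = 0, block_area_um2 = 1), 0)

  # diagonal touch is one region under 8-connectivity
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  regs <- label_regions(m, 1:5 * 12, 1:5 * 12, min_area_um2 = 0,
                        block_area_um2 = 1)
  expect_length(regs, 1)
  expect_equal(regs[[1]]$area_um2, 2)

  # random masks vs igraph connected components (independent oracle)
  set.seed(91)
  for (i in 1:10) {
    mk <- matrix(runif(100) < 0.4, 10, 10)
    regs <- label_regions(mk, 1:10 * 12, 1:10 * 12, min_area_um2 = 0,
                          block_area_um2 = 1)
    cells <- which(mk)
    if (length(cells) == 0) { expect_length(regs, 0); next }
    pos <- arrayInd(cells, dim(mk))
    edges <- integer(0)
    for (a in seq_along(cells)) for (b in seq_along(cells)) {
      if (a < b && max(abs(pos[a, ] - pos[b, ])) <= 1)
        edges <- c(edges, a, b)
    }
    g <- igraph::make_graph(edges, n = length(cells), directed = FALSE)
    comp <- igraph::components(g)
    expect_equal(length(regs), comp$no)
    sizes <- sort(vapply(regs, function(r) length(r$cells), numeric(1)))
    expect_equal(sizes, sort(unname(comp$csize)))
  }

  # area filter drops small components
  m2 <- matrix(FALSE, 6, 6); m2[1, 1] <- TRUE; m2[4:6, 4:6] <- TRUE
  kept <- label_regions(m2, 1:6 * 12, 1:6 * 12, min_area_um2 = 5,
                        block_area_um2 = 1)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$area_um2, 9)
})

test_that("cycle segmentation delimits maximal active runs", {
  expect_equal(nrow(segment_cycles(rep(FALSE, 10))), 0)

  act <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE)
  cyc <- segment_cycles(act)
  expect_equal(nrow(cyc), 3)
  expect_equal(cyc$start, c(2, 6, 8))
  expect_equal(cyc$end, c(3, 6, 10))            # final run closed at the end
})

test_that("tree construction follows growth, merges, and singletons", {
  # one region growing monotonically over 5 frames -> single path
  disk <- function(r, c0 = 8) {
    m <- matrix(FALSE, 15, 15)
    for (i in 1:15) for (j in 1:15)
      if ((i - c0)^2 + (j - c0)^2 <= r^2) m[i, j] <- TRUE
    m
  }
  fields <- lapply(1:5, function(t) field_from_mask(disk(t), frame = t))
  fit <- fake_fit(fields)
  blk <- (12 * 0.9616)^2
  fo <- contraction_forest(fit, contraction_criteria(
    min_region_area_um2 = 0, block_area_um2 = blk, norm_area_um2 = blk))
  expect_equal(nrow(fo$nodes), 5)
  expect_equal(sum(fo$nodes$is_root), 1)
  expect_equal(sum(fo$nodes$is_leaf), 1)
  leaf <- fo$nodes[fo$nodes$is_leaf, ]
  expect_equal(leaf$frame, 1)
  expect_equal(leaf$depth, 4)
  expect_equal(fo$nodes$frame[fo$nodes$is_root], 5)
  # depth consistency along every edge
  for (k in seq_len(nrow(fo$edges))) {
    p <- fo$nodes[match(fo$edges$parent_id[k], fo$nodes$id), ]
    ch <- fo$nodes[match(fo$edges$child_id[k], fo$nodes$id), ]
    expect_equal(ch$depth, p$depth + 1)
    expect_gt(p$frame, ch$frame)
  }
  # ASC peak equals the leaf depth at the origin
  asc <- asc_map(fo)
  expect_equal(max(asc), 4)
  expect_equal(asc[8, 8], 4)

  # two regions merging -> 2 leaves, 1 root
  two <- matrix(FALSE, 15, 15); two[4:6, 4:6] <- TRUE; two[10:12, 10:12] <- TRUE
  merged <- matrix(FALSE, 15, 15); merged[3:13, 3:13] <- TRUE
  fit2 <- fake_fit(list(field_from_mask(two, frame = 1),
                        field_from_mask(merged, frame = 2)))
  fo2 <- contraction_forest(fit2, contraction_criteria(
    min_region_area_um2 = 0, block_area_um2 = blk, norm_area_um2 = blk))
  expect_equal(sum(fo2$nodes$is_leaf), 2)
  expect_equal(sum(fo2$nodes$is_root), 1)
  expect_equal(sort(fo2$nodes$depth), c(0, 1, 1))

  # an isolated single-frame region is a singleton (leaf = root, depth 0)
  lone <- matrix(FALSE, 15, 15); lone[7:9, 7:9] <- TRUE
  fit3 <- fake_fit(list(field_from_mask(matrix(FALSE, 15, 15), frame = 1),
                        field_from_mask(lone, frame = 2),
                        field_from_mask(matrix(FALSE, 15, 15), frame = 3)))
  fo3 <- contraction_forest(fit3, contraction_criteria(
    min_region_area_um2 = 0, block_area_um2 = blk, norm_area_um2 = blk))
  expect_equal(nrow(fo3$nodes), 1)
  expect_true(fo3$nodes$is_singleton[1])
  expect_equal(fo3$nodes$depth[1], 0)
  # all-singleton forest has no ranked origins
  expect_equal(nrow(find_origins(fo3)), 0)
  # empty forest gives an all-zero map
  fit4 <- fake_fit(list(field_from_mask(matrix(FALSE, 15, 15), frame = 1),
                        field_from_mask(matrix(FALSE, 15, 15), frame = 2)))
  fo4 <- contraction_forest(fit4, contraction_criteria(
    min_region_area_um2 = 0, block_area_um2 = blk, norm_area_um2 = blk))
  expect_equal(nrow(fo4$nodes), 0)
  expect_true(all(asc_map(fo4) == 0))
})

test_that("forest invariants hold on a measured fixture", {
  to <- three_origin_fit()
  fo <- to$forest
  nd <- fo$nodes
  # every node in exactly one tree: each non-root has one parent, parents
  # are in the same cycle, and each member set is non-empty
  expect_true(all(!is.na(nd$parent[!nd$is_root])))
  pc <- nd$cycle[match(nd$parent[!nd$is_root], nd$id)]
  expect_equal(pc, nd$cycle[!nd$is_root])
  expect_true(all(vapply(fo$members, length, numeric(1)) > 0))
  for (k in seq_len(nrow(fo$edges))) {
    p <- match(fo$edges$parent_id[k], nd$id)
    ch <- match(fo$edges$child_id[k], nd$id)
    expect_equal(nd$depth[ch], nd$depth[p] + 1)
  }
  # ASC max equals the forest's max depth
  expect_equal(max(asc_map(fo)), max(nd$depth))
})

test_that("origins are recovered with correct count, location, and lag", {
  to <- three_origin_fit()
  or <- find_origins(to$forest)
  expect_equal(nrow(or), 3)
  truth_xy <- cbind(c(70, 186, 128), c(70, 70, 186)) * 0.9616
  cell_um <- 12 * 0.9616
  for (k in 1:3) {
    d <- sqrt((or$x_um - truth_xy[k, 1])^2 + (or$y_um - truth_xy[k, 2])^2)
    expect_lt(min(d), cell_um)
  }
  # staggered onsets (0, 2, 4 frames) rank the origins in onset order
  expect_lt(abs(or$x_um[1] - truth_xy[1, 1]), cell_um)
  expect_lt(abs(or$x_um[2] - truth_xy[2, 1]), cell_um)

  oo <- origin_onsets(to$forest)
  first <- aggregate(onset_s ~ origin_rank + cycle, oo, min)
  lags12 <- with(first, tapply(onset_s, cycle, function(v) v[2] - v[1]))
  expect_equal(mean(lags12), 0.4, tolerance = 0.2)
})

test_that("ASTC tables round-trip through CSV", {
  sb <- slow_beat_fit()
  at <- astc_table(sb$forest)
  expect_true(all(c("id", "x_um", "y_um", "t_s", "depth", "cycle_id",
                    "is_origin", "is_singleton") %in% names(at$nodes)))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(at$edges, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$parent_id, at$edges$parent_id)
  expect_equal(back$child_id, at$edges$child_id)
})
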