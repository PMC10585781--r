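test_that("Manhattan distance follows the city-block definition", {
  expect_equal(spatial_distance(c(0, 0), c(3, 4)), 7)
  expect_equal(spatial_distance(c(5, 2), c(5, 2)), 0)
  expect_equal(spatial_distance(c(10, 10), c(10, 21)), 11)
})

test_that("the root is the segment starting nearest the upper-left corner", {
  a <- seg_stub(1, c(5, 5), c(50, 50), 40)
  b <- seg_stub(2, c(100, 3), c(150, 40), 40)
  expect_equal(find_root(list(a, b)), 1L)
  expect_equal(find_root(list(b)), 1L)
  # tie at distance 10: smaller y wins
  c1 <- seg_stub(1, c(10, 0), c(60, 40), 40)
  c2 <- seg_stub(2, c(0, 10), c(40, 60), 40)
  expect_equal(find_root(list(c2, c1)), 2L)
  expect_error(find_root(list()), "no segments")
})

test_that("children order by the cross-product sign with a collinear tie rule", {
  expect_equal(order_children(c(0, 0), rbind(c(1, 0), c(1, 1))), c(1L, 2L))
  expect_equal(order_children(c(0, 0), rbind(c(1, 1), c(1, 0))), c(2L, 1L))
  # collinear: ascending x then y
  expect_equal(order_children(c(0, 0), rbind(c(2, 2), c(1, 1))), c(2L, 1L))
  expect_equal(order_children(c(0, 0), rbind(c(4, 0))), 1L)
})

test_that("tree attachment honours the inclusive 10-px threshold", {
  parent <- seg_stub(1, c(5, 5), c(50, 50), 60)
  child_in <- seg_stub(2, c(54, 56), c(90, 90), 50)    # d_n = 10
  child_out <- seg_stub(3, c(54, 57), c(90, 95), 50)   # d_n = 11
  tr <- build_tree(list(parent, child_in, child_out))
  by_parent <- vapply(tr$nodes, function(nd) nd$parent, integer(1))
  # exactly one attached child; the other becomes an orphan root
  expect_equal(sum(!is.na(by_parent)), 1L)
  expect_length(tr$root_ids, 2L)
  attached <- tr$nodes[[which(!is.na(by_parent))]]$segment
  expect_equal(unname(attached$start), c(54, 56))
})

test_that("a node keeps at most the three nearest children", {
  parent <- seg_stub(1, c(0, 0), c(50, 50), 60)
  kids <- lapply(1:4, function(i) {
    seg_stub(i + 1, c(50 + i, 50 + i), c(100 + i, 100), 50)
  })
  tr <- build_tree(c(list(parent), kids))
  root_node <- tr$nodes[[tr$root_ids[1]]]
  expect_lte(length(root_node$children), 3L)
  # the farthest candidate (d_n = 8) is the orphan
  orphan <- setdiff(seq_along(tr$nodes), c(tr$root_ids[1], root_node$children))
  starts <- lapply(orphan, function(i) tr$nodes[[i]]$segment$start)
  expect_true(any(vapply(starts, function(s) all(s == c(54, 54)), logical(1))))
})

test_that("IDs increase from root down the levels", {
  parent <- seg_stub(1, c(5, 5), c(50, 50), 60)
  k1 <- seg_stub(2, c(52, 52), c(90, 30), 45)
  k2 <- seg_stub(3, c(51, 53), c(90, 90), 45)
  g1 <- seg_stub(4, c(91, 30), c(130, 20), 40)
  tr <- build_tree(list(g1, k2, parent, k1))
  lv <- vapply(tr$nodes, function(nd) nd$level, integer(1))
  expect_equal(tr$root_ids, 1L)
  # id order must be non-decreasing in level: smaller id = earlier vessel
  expect_true(all(lv == sort(lv)))
})

test_that("phantom trees are recovered edge-for-edge with geometric child order", {
  for (seed in 1:8) {
    spec <- random_tree_spec(seed = seed, n_internal = 2L)
    m <- render_vessel_mask(spec, 0L)
    res <- skeletonize(m)
    segs <- describe_segments(m, res$paths, res$keypoints$intersections)
    sq <- make_sequence(spec)
    tsegs <- sq$truth$frames[[1]]$segments
    expect_length(segs, length(tsegs))
    tr <- build_tree(segs)
    mp <- map_to_truth(tr$segments, tsegs)
    expect_false(any(duplicated(mp)))
    redges <- c(); tedges <- c()
    for (i in seq_along(tr$nodes)) {
      p <- tr$nodes[[i]]$parent
      if (!is.na(p)) redges <- c(redges, paste(mp[p], mp[i]))
    }
    for (i in seq_along(tsegs)) {
      p <- tsegs[[i]]$parent
      if (!is.na(p)) tedges <- c(tedges, paste(p, i))
    }
    expect_setequal(redges, tedges)
    # child order agrees with the cross-product sign computed from truth
    for (i in seq_along(tr$nodes)) {
      ch <- tr$nodes[[i]]$children
      if (length(ch) == 2) {
        p1 <- as.numeric(tr$nodes[[i]]$segment$end)
        k1 <- min(12L, nrow(tsegs[[mp[ch[1]]]]$centerline))
        k2 <- min(12L, nrow(tsegs[[mp[ch[2]]]]$centerline))
        s1 <- tsegs[[mp[ch[1]]]]$centerline[k1, ]  # a few px past the fork
        s2 <- tsegs[[mp[ch[2]]]]$centerline[k2, ]
        V <- (s1[1] - p1[1]) * (s2[2] - s1[2]) - (s1[2] - p1[2]) * (s2[1] - s1[1])
        expect_gte(V, 0)
      }
    }
  }
})
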