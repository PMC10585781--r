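test_that("thinning leaves already-thin structures alone", {
  line <- matrix(0L, 5, 12)
  line[3, 2:11] <- 1L
  expect_identical(thin(line), line)

  dot <- matrix(0L, 5, 5)
  dot[3, 3] <- 1L
  expect_identical(thin(dot), dot)

  empty <- matrix(0L, 6, 6)
  expect_identical(thin(empty), empty)
})

test_that("thinning a filled bar gives its 1-px centerline", {
  m <- bar_mask(height = 3L, length = 21L)
  sk <- thin(m)
  on <- which(sk == 1L, arr.ind = TRUE)
  expect_true(all(on[, "row"] == 6L))  # middle row of rows 5:7
  expect_identical(sk, zs_thin_oracle(m))
})

test_that("thinning matches the naive pixel-by-pixel oracle and is idempotent", {
  set.seed(7)
  for (i in 1:10) {
    m <- random_mask(sample(12:48, 1), sample(12:48, 1))
    sk <- thin(m)
    expect_identical(sk, zs_thin_oracle(m))
    expect_identical(thin(sk), sk)
  }
})

test_that("staircase removal deletes step corners but keeps straight runs", {
  line <- matrix(0L, 5, 12)
  line[3, 2:11] <- 1L
  expect_identical(remove_staircase(line), line)

  # corner pixel with neighbours above and left; removal keeps the two
  # neighbours diagonally connected
  m <- matrix(0L, 7, 7)
  m[2, 3] <- 1L  # (x, y) = (2, 1)
  m[3, 3] <- 1L  # corner (2, 2): above is (2,1), left is (1,2)
  m[3, 2] <- 1L
  m[4, 2] <- 1L
  out <- remove_staircase(m)
  expect_equal(out[3, 3], 0L)
  expect_equal(angiotrack:::label_components(out)$n,
               angiotrack:::label_components(m)$n)
})

test_that("staircase removal never disconnects a component", {
  set.seed(11)
  for (i in 1:8) {
    sk <- thin(random_mask(sample(16:40, 1), sample(16:40, 1)))
    out <- remove_staircase(sk)
    expect_equal(angiotrack:::label_components(out)$n,
                 angiotrack:::label_components(sk)$n)
  }
})

test_that("keypoints on plus, T and Y fixtures are exact", {
  kp <- detect_keypoints(plus_mask())
  expect_equal(nrow(kp$endpoints), 4L)
  expect_equal(nrow(kp$intersections), 1L)
  expect_equal(unname(kp$intersections[1, ]), c(5, 5))

  kt <- detect_keypoints(t_mask())
  expect_equal(nrow(kt$endpoints), 3L)
  expect_equal(nrow(kt$intersections), 1L)
  expect_equal(unname(kt$intersections[1, ]), c(5, 1))

  ky <- detect_keypoints(y_mask())
  expect_equal(nrow(ky$endpoints), 3L)
  expect_equal(nrow(ky$intersections), 1L)
  expect_equal(unname(ky$intersections[1, ]), c(5, 5))
})

test_that("a short open line has two endpoints and no intersections", {
  m <- matrix(0L, 5, 7)
  m[3, 3:5] <- 1L
  kp <- detect_keypoints(m)
  expect_equal(nrow(kp$endpoints), 2L)
  expect_equal(nrow(kp$intersections), 0L)
})

test_that("splitting partitions skeletons at junctions", {
  expect_length(split_segments(y_mask()), 3L)
  expect_length(split_segments(plus_mask()), 4L)
  curve <- matrix(0L, 9, 9)
  curve[2, 2:6] <- 1L
  curve[3:7, 6] <- 1L   # L-shaped open curve: still one path
  expect_length(split_segments(curve), 1L)
})

test_that("every non-junction skeleton pixel lands in exactly one path", {
  set.seed(3)
  sk <- remove_staircase(thin(random_mask(40, 40)))
  paths <- split_segments(sk)
  seen <- matrix(0L, nrow(sk), ncol(sk))
  for (p in paths) {
    pix <- p$pixels
    own <- seq_len(nrow(pix))
    if (isTRUE(p$junction_start)) own <- own[-1]
    if (isTRUE(p$junction_end)) own <- own[-length(own)]
    for (i in own) seen[pix[i, 2] + 1, pix[i, 1] + 1] <- seen[pix[i, 2] + 1, pix[i, 1] + 1] + 1L
  }
  expect_true(all(seen[seen > 0] == 1L))
})

test_that("burr removal drops short spurs, keeps length-6 and interior arcs", {
  mk <- function(n, js = FALSE, je = FALSE) {
    list(pixels = cbind(x = seq_len(n), y = rep(1L, n)),
         junction_start = js, junction_end = je, closed = FALSE,
         frame_index = 0L)
  }
  out <- remove_burrs(list(mk(4), mk(10)))
  expect_length(out, 1L)
  expect_equal(path_length(out[[1]]), 10L)
  expect_length(remove_burrs(list(mk(6))), 1L)      # strict less-than
  expect_length(remove_burrs(list()), 0L)
  # interior junction-to-junction arcs are not spurs
  expect_length(remove_burrs(list(mk(5, js = TRUE, je = TRUE))), 1L)
})

test_that("repair restores interior pieces but never terminal spurs", {
  # horizontal centerline with two spurs (former junctions at x = 9 and
  # x = 15 on row y = 4); the interior piece between the junctions was
  # deleted along with the spurs
  bar <- matrix(0L, 9, 25)
  bar[5, 2:24] <- 1L
  orig <- bar
  orig[2:4, 10] <- 1L   # spur above x = 9
  orig[2:4, 16] <- 1L   # spur above x = 15
  deb <- bar
  deb[5, 12:14] <- 0L   # interior piece x = 11..13 removed
  out <- repair(orig, deb)
  expect_equal(out[5, 12:14], c(1L, 1L, 1L))           # interior restored
  expect_equal(sum(out[2:4, 10]), 0L)                  # spurs stay removed
  expect_equal(sum(out[2:4, 16]), 0L)

  # nothing to restore when deburred equals original
  expect_identical(repair(bar, bar), bar)

  # deleted pixels far from any deburred endpoint are never restored
  iso <- bar
  iso[2, 20] <- 1L
  out2 <- repair(iso, bar)
  expect_equal(out2[2, 20], 0L)
})

test_that("the full skeleton stage rejoins vessels wrongly split by a spur", {
  m <- bar_mask(height = 5L, length = 40L, pad = 6L)
  # short spur poking up from the bar mid-way; its skeleton branch is
  # shorter than the burr threshold
  m[4:6, 26] <- 1L
  res <- skeletonize(m)
  expect_length(res$paths, 1L)
  expect_gte(path_length(res$paths[[1]]), 30L)
})
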