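test_that("spec validation names the offending field", {
  seg <- list(points = rbind(c(10, 10), c(80, 80)), base_width = 5, parent = NA)
  expect_error(
    phantom_spec(128, 128, segments = list(modifyList(seg, list(base_width = 2)))),
    "base_width")
  expect_error(
    phantom_spec(128, 128, segments = list(seg),
                 stenoses = list(list(segment = 1, position = 0.5,
                                      severity = 1.0, extent = 20))),
    "severity")
  expect_error(
    phantom_spec(128, 128, segments = list(seg), n_frames = 0), "n_frames")
  # child must start near the parent's endpoint
  far_child <- list(points = rbind(c(0, 0), c(40, 0)), base_width = 4, parent = 1)
  expect_error(phantom_spec(128, 128, segments = list(seg, far_child)),
               "parent endpoint")
  expect_warning(
    phantom_spec(128, 128, segments = list(seg), motion_per_frame = c(40, 30),
                 n_frames = 2), "matching will fail")
})

test_that("rendering is deterministic and produces the expected area", {
  spec <- straight_vessel_spec(width = 5, angle_deg = 0, length = 100, size = 128)
  m1 <- render_vessel_mask(spec, 0L)
  m2 <- render_vessel_mask(spec, 0L)
  expect_identical(m1, m2)
  expect_lte(abs(sum(m1) - 500) / 500, 0.1)
  expect_error(render_vessel_mask(spec, 1L), "n_frames")
})

test_that("same seed gives identical sequences; frames translate rigidly", {
  spec <- random_tree_spec(seed = 4, n_internal = 2, motion_per_frame = c(3, 3),
                           n_frames = 5)
  s1 <- make_sequence(spec)
  s2 <- make_sequence(random_tree_spec(seed = 4, n_internal = 2,
                                       motion_per_frame = c(3, 3), n_frames = 5))
  expect_identical(s1$masks, s2$masks)
  expect_identical(s1$truth, s2$truth)
  # truth correspondence links every segment in all frames
  for (t in 1:5) {
    ids <- vapply(s1$truth$frames[[t]]$segments, function(s) s$correspondence_id,
                  integer(1))
    expect_equal(sort(ids), seq_along(spec$segments))
  }
  # centerlines shift by exactly t * motion
  cl0 <- s1$truth$frames[[1]]$segments[[1]]$centerline
  cl3 <- s1$truth$frames[[4]]$segments[[1]]$centerline
  expect_equal(cl3 - cl0, matrix(9, nrow(cl0), 2), ignore_attr = TRUE)
})

test_that("periodic lesions oscillate between zero and full severity", {
  spec <- straight_vessel_spec(
    width = 8, angle_deg = 30, length = 90, size = 144, n_frames = 12,
    stenoses = list(list(segment = 1, position = 0.5, severity = 0.5,
                         extent = 20, periodic = TRUE, period_frames = 6)))
  sq <- make_sequence(spec)
  deg <- vapply(sq$truth$frames, function(fr) fr$lesions[[1]]$degree, numeric(1))
  expect_equal(max(deg), 0.5, tolerance = 1e-9)
  expect_equal(min(deg), 0, tolerance = 1e-9)
  expect_true(sq$truth$lesion_bridge[1])
})

test_that("rendered width matches the distance-transform oracle on the centerline", {
  for (w in c(5, 9)) {
    spec <- straight_vessel_spec(width = w, angle_deg = 15, length = 80, size = 128)
    m <- render_vessel_mask(spec, 0L)
    sq <- make_sequence(spec)
    cl <- sq$truth$frames[[1]]$segments[[1]]$centerline
    interior <- cl[6:(nrow(cl) - 5), , drop = FALSE]
    oracle <- 2 * edt_at(m, interior)
    expect_gte(mean(abs(oracle - w) <= 1), 0.95)
  }
})

test_that("truth bifurcation count equals parents with two or more children", {
  spec <- random_tree_spec(seed = 6, n_internal = 2)
  sq <- make_sequence(spec)
  parents <- vapply(spec$segments, function(s) {
    if (is.null(s$parent)) NA_integer_ else as.integer(s$parent)
  }, integer(1))
  n_bif <- sum(table(parents[!is.na(parents)]) >= 2)
  expect_equal(nrow(sq$truth$frames[[1]]$bifurcations), n_bif)
})

test_that("phantom files round-trip bit-identically", {
  spec <- random_tree_spec(seed = 2, n_internal = 1, motion_per_frame = c(2, 1),
                           n_frames = 3)
  sq <- make_sequence(spec)
  d <- withr::local_tempdir()
  write_phantom(d, sq$masks, sq$truth)
  expect_setequal(list.files(d),
                  c("frame_0000.png", "frame_0001.png", "frame_0002.png",
                    "truth.json"))
  back <- read_mask_sequence(d)
  expect_identical(back, sq$masks)
  tj <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(tj$n_frames, 3L)
  expect_length(tj$frames, 3L)
  expect_error(write_phantom(d, list(), sq$truth), "no frames")
})
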