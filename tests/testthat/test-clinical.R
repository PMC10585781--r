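test_that("trailing moving average shrinks at the left edge", {
  expect_equal(smooth_profile(c(1, 2, 3, 4), 3), c(1, 1.5, 2, 3))
  expect_equal(smooth_profile(rep(4.2, 9), 5), rep(4.2, 9))
  expect_equal(smooth_profile(c(2, 9, 4), 1), c(2, 9, 4))
  expect_error(smooth_profile(c(1, 2), 3), "exceeds")
  expect_error(smooth_profile(1:10, 4), "odd")
})

test_that("percent stenosis follows the closed form and is monotone", {
  expect_equal(stenosis_percent(3, 10, 10), 70)
  expect_equal(stenosis_percent(5, 5, 5), 0)
  set.seed(2)
  for (i in 1:25) {
    Df <- runif(1, 5, 15); Db <- runif(1, 5, 15)
    Dm <- runif(1, 0.5, min(Df, Db))
    expect_equal(stenosis_percent(Dm, Df, Db), (1 - 2 * Dm / (Df + Db)) * 100)
    # increasing D_min with fixed flanks strictly decreases P
    expect_lt(stenosis_percent(Dm + 0.5, Df, Db), stenosis_percent(Dm, Df, Db))
  }
})

test_that("grading bands are lower-inclusive with a normal class below 30", {
  expect_equal(grade_stenosis(79.3), "severe")
  expect_equal(grade_stenosis(70), "severe")
  expect_equal(grade_stenosis(69.9), "moderate")
  expect_equal(grade_stenosis(50), "moderate")
  expect_equal(grade_stenosis(49.9), "mild")
  expect_equal(grade_stenosis(30), "mild")
  expect_equal(grade_stenosis(29.9), "normal")
  expect_equal(grade_label(c("mild", "moderate", "severe")), 0:2)
  expect_true(is.na(grade_label("normal")))
})

test_that("stenosis candidates come from profile minima with flanking maxima", {
  prof <- list(values = c(10, 10, 9, 6, 3, 6, 9, 10, 10), positions = 1:9)
  q <- quantify_stenosis(prof, peripheral = FALSE)
  expect_equal(nrow(q), 1L)
  expect_equal(q$D_min, 3)
  expect_equal(q$P, 70)
  expect_equal(q$grade, "severe")

  # flat profile: P = 0, discarded as normal
  flat <- list(values = rep(8, 9), positions = 1:9)
  expect_equal(nrow(quantify_stenosis(flat, peripheral = FALSE)), 0L)

  # monotone profile has no interior minimum
  mono <- list(values = seq(10, 2, length.out = 9), positions = 1:9)
  expect_equal(nrow(quantify_stenosis(mono, peripheral = FALSE)), 0L)
})

test_that("peripheral vessels ignore the tapering distal fifth", {
  # a dip inside the distal 20% must not be called
  v <- c(10, 10, 10, 10, 10, 10, 10, 10, 4, 10)
  q <- quantify_stenosis(list(values = v, positions = 1:10), peripheral = TRUE,
                         floor = 0)
  expect_equal(nrow(q), 0L)
  # the same dip mid-vessel is called
  v2 <- c(10, 10, 10, 4, 10, 10, 10, 10, 10, 10)
  q2 <- quantify_stenosis(list(values = v2, positions = 1:10), peripheral = TRUE)
  expect_equal(nrow(q2), 1L)
  expect_equal(q2$D_min, 4)
})

test_that("phantom lesions are quantified near their programmed severity", {
  spec <- straight_vessel_spec(
    width = 10, angle_deg = 20, length = 100, size = 160,
    stenoses = list(list(segment = 1, position = 0.5, severity = 0.5,
                         extent = 24, periodic = FALSE, period_frames = 1)))
  m <- render_vessel_mask(spec, 0L)
  rep <- run_pipeline(list(m))
  expect_gte(length(rep$stenoses), 1L)
  best <- max(vapply(rep$stenoses, function(s) s$P, numeric(1)))
  expect_lte(abs(best - 50), 10)
})

test_that("bridge rules fire on stenosis swings or diameter drops, gap >= 3", {
  cfg <- angio_config()
  tsA <- data.frame(frame = 0:4, id = 1,
                    degree = c(0.20, 0.25, 0.30, 0.35, 0.50),
                    mean_diameter = rep(10, 5))
  bA <- detect_bridge(tsA, cfg)
  expect_equal(bA$rule, "stenosis_variation")
  expect_equal(bA$stenosis_max - bA$stenosis_min, 0.30)

  # constant stenosis never fires
  tsC <- data.frame(frame = 0:4, id = 1, degree = rep(0.5, 5),
                    mean_diameter = rep(10, 5))
  expect_null(detect_bridge(tsC, cfg))

  tsB <- data.frame(frame = 0:4, id = 1, degree = rep(0.1, 5),
                    mean_diameter = c(10, 10, 9, 8, 7))
  bB <- detect_bridge(tsB, cfg)
  expect_equal(bB$rule, "diameter_ratio")

  # sufficient swing but extreme frames only 1 apart: gap rule blocks it
  tsG <- data.frame(frame = 0:4, id = 1,
                    degree = c(0.3, 0.3, 0.45, 0.1, 0.3),
                    mean_diameter = rep(10, 5))
  expect_null(detect_bridge(tsG, cfg))

  # short tracks never fire
  expect_null(detect_bridge(tsA[1:3, ], cfg))
})

test_that("periodic phantom lesions are flagged and static ones are not", {
  for (seed in 1:3) {
    per <- make_sequence(bridge_case_spec(seed = seed, periodic = TRUE,
                                          severity = 0.5, period_frames = 6,
                                          n_frames = 12))
    rep_per <- run_pipeline(per$masks)
    expect_gte(length(rep_per$bridges), 1L)

    sta <- make_sequence(bridge_case_spec(seed = seed, periodic = FALSE,
                                          severity = 0.5, period_frames = 6,
                                          n_frames = 12))
    rep_sta <- run_pipeline(sta$masks)
    expect_length(rep_sta$bridges, 0L)
  }
})
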