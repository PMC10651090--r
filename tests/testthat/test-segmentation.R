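test_that("foreground excludes white background and saturated pixels", {
  rec <- two_tone_record()
  fg <- foreground_mask(rec)
  expect_equal(fg, rec$roi)  # animal fills the ROI; background is outside

  # widen the ROI over white background: those pixels must be excluded
  wide <- rec
  wide$roi[12:37, 18:53] <- TRUE
  fg2 <- foreground_mask(wide)
  expect_equal(sum(fg2), sum(rec$roi))

  # an all-white ROI has no animal
  blank <- two_tone_record(dark = c(0.98, 0.98, 0.98), light = c(0.98, 0.98, 0.98))
  expect_error(foreground_mask(blank), "foreground")
})

test_that("k-means++ must pick both modes of a two-point cloud", {
  px <- rbind(matrix(0, 50, 3), matrix(1, 50, 3))
  for (seed in 1:5) {
    ctr <- kmeanspp_init(px, 2, seed = seed)
    # D^2 weighting gives zero mass to the already-chosen value
    expect_setequal(ctr[, 1], c(0, 1))
  }
  expect_error(kmeanspp_init(matrix(0.5, 10, 3), 2), "distinct")
  set.seed(1)
  cloud <- matrix(runif(90), 30, 3)
  expect_identical(kmeanspp_init(cloud, 3, seed = 9),
                   kmeanspp_init(cloud, 3, seed = 9))
})

test_that("Lloyd iterations converge with non-increasing inertia", {
  px <- cbind(c(0, 0, 1, 1), 0, 0)
  fit <- kmeans_lloyd(px, rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(fit$inertia, 0)
  expect_equal(sort(fit$centers[, 1]), c(0, 1))

  # k = 1: the center is the mean
  set.seed(3)
  px <- matrix(runif(60), 20, 3)
  fit1 <- kmeans_lloyd(px, matrix(runif(3), 1, 3))
  expect_equal(as.numeric(fit1$centers), colMeans(px))

  fitn <- kmeans_lloyd(px, px[1:3, ])
  expect_true(all(diff(fitn$inertia_history) <= 1e-9))
})

test_that("an emptied cluster is re-seeded at the farthest point", {
  # duplicated initial centers: ties send every point to cluster 1,
  # leaving cluster 2 empty on the first assignment
  px <- cbind(c(rep(0, 10), rep(0.9, 5)), 0, 0)
  fit <- kmeans_lloyd(px, rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_setequal(round(sort(fit$centers[, 1]), 6), c(0, 0.9))
  expect_equal(fit$inertia, 0)
})

test_that("converged 2-means equals the exhaustive optimal 1-D partition", {
  set.seed(11)
  for (rep in 1:3) {
    x <- c(runif(30, 0, 0.35), runif(30, 0.55, 1))
    px <- cbind(x, x, x)  # gray pixels: 1-D structure embedded in RGB
    best <- Inf
    for (s in 1:10) {
      fit <- kmeans_lloyd(px, kmeanspp_init(px, 2, seed = s))
      best <- min(best, fit$inertia)
    }
    expect_equal(best, 3 * best_2partition_inertia(x), tolerance = 1e-9)
  }
})

test_that("two-tone foreground is split exactly, darker cluster = melanistic", {
  rec <- two_tone_record()
  seg <- segment_pattern(rec, seg_config(seed = 1))
  truth_dark <- matrix(FALSE, 40, 60); truth_dark[15:34, 21:35] <- TRUE
  expect_equal(seg$melanistic_mask, truth_dark)
  expect_false(seg$low_contrast)

  # label-swap invariance: the melanistic side follows center luminance,
  # never cluster index, for any seed
  for (seed in 2:6)
    expect_equal(segment_pattern(rec, seg_config(seed = seed))$melanistic_mask,
                 truth_dark)
})

test_that("uniform or near-uniform foreground is flagged low-contrast", {
  rec <- two_tone_record(dark = c(0.9, 0.8, 0.3), light = c(0.9, 0.8, 0.3))
  seg <- segment_pattern(rec, seg_config(seed = 2))
  expect_true(seg$low_contrast)
  expect_equal(sum(seg$melanistic_mask), 0)

  # two tones closer than the contrast threshold: also no pattern call
  rec2 <- two_tone_record(dark = c(0.88, 0.78, 0.3), light = c(0.9, 0.8, 0.3))
  seg2 <- segment_pattern(rec2, seg_config(seed = 2))
  expect_true(seg2$low_contrast)
  expect_equal(sum(seg2$melanistic_mask), 0)
})

test_that("segmentation is deterministic given image, config and seed", {
  gi <- generate_image(image_gen_params(target_proportion = 0.15, seed = 5))
  s1 <- segment_pattern(gi$record, seg_config(seed = 3))
  s2 <- segment_pattern(gi$record, seg_config(seed = 3))
  expect_identical(s1$melanistic_mask, s2$melanistic_mask)
  expect_identical(s1$centers, s2$centers)
})

test_that("foreground tracks the generator's true body mask", {
  gi <- generate_image(image_gen_params(target_proportion = 0.2, seed = 8))
  seg <- segment_pattern(gi$record, seg_config(seed = 1))
  jac <- sum(seg$foreground_mask & gi$body_mask) /
    sum(seg$foreground_mask | gi$body_mask)
  expect_gte(jac, 0.95)
})

test_that("bisecting recursion keeps the top-level class call", {
  gi <- generate_image(image_gen_params(target_proportion = 0.25, seed = 2))
  flat <- segment_pattern(gi$record, seg_config(seed = 1))
  deep <- segment_pattern(gi$record, seg_config(seed = 1, max_depth = 2))
  expect_equal(deep$melanistic_mask, flat$melanistic_mask)
  expect_length(deep$leaves, 2)
})
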