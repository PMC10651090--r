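test_that("pattern metrics on a half-dark foreground", {
  rec <- two_tone_record()
  seg <- segment_pattern(rec, seg_config(seed = 1))
  pm <- pattern_metrics(rec, seg)
  expect_equal(pm$melanistic_proportion, 0.5)
  expect_lt(pm$mean_lum_mel, pm$mean_lum_nonmel)
  expect_equal(pm$mean_lum_mel, luminance(c(0.1, 0.1, 0.1)))
  expect_equal(pm$mean_lum_nonmel, luminance(c(0.9, 0.8, 0.3)))
})

test_that("low-contrast images get proportion 0 and undefined melanistic luminance", {
  rec <- two_tone_record(dark = c(0.9, 0.8, 0.3), light = c(0.9, 0.8, 0.3))
  seg <- segment_pattern(rec, seg_config(seed = 1))
  pm <- pattern_metrics(rec, seg)
  expect_equal(pm$melanistic_proportion, 0)
  expect_true(is.na(pm$mean_lum_mel))
  expect_false(is.na(pm$mean_lum_nonmel))
})

test_that("individual summaries: mean, sample SD, and guarded log", {
  m <- function(p) data.frame(individual_id = "a", melanistic_proportion = p)
  s1 <- summarize_individual(m(c(0.2, 0.2, 0.2)))
  expect_equal(s1$mean_proportion, 0.2)
  expect_equal(s1$sd_proportion, 0)
  s2 <- summarize_individual(m(c(0.1, 0.2, 0.3)))
  expect_equal(s2$mean_proportion, 0.2)
  expect_equal(s2$sd_proportion, 0.1)  # hand sample-SD
  expect_equal(s2$log_mean_proportion, log(0.2))
  s3 <- summarize_individual(m(c(0, 0, 0)))
  expect_true(is.na(s3$log_mean_proportion))
  expect_false(s3$log_defined)
  empty <- data.frame(individual_id = character(0),
                      melanistic_proportion = numeric(0))
  expect_error(summarize_individual(empty), "no accepted images")
})

test_that("body temperature is the eye average with a snout fallback", {
  expect_equal(body_temperature(list(eye_L = 30.0, eye_R = 30.4)), 30.2)
  expect_warning(bt <- body_temperature(list(eye_L = NA, eye_R = NA, snout = 29.8)),
                 "snout")
  expect_equal(bt, 29.8)
  expect_error(body_temperature(list(eye_L = NA, eye_R = NA, snout = NA)),
               "missing")
})

test_that("thermal table validation and the zero-datalogger flag", {
  co <- generate_thermal_cohort(thermal_gen_params(seed = 4))
  th <- read_thermal(co$thermal)
  expect_equal(nrow(th), 180)
  expect_equal(sum(is.finite(th$body_temp)), 178)   # two dropped IR images
  expect_equal(sum(th$dl_valid), 179)               # one zero reading removed
  ok <- is.finite(th$eye_L)
  expect_equal(th$body_temp[ok], (th$eye_L[ok] + th$eye_R[ok]) / 2)

  bad <- co$thermal; bad$eye_L[3] <- 60
  expect_error(read_thermal(bad), "plausible")
  expect_error(read_thermal(co$thermal[, -3]), "missing columns")
  bad2 <- co$thermal; bad2$block[1] <- 7
  expect_error(read_thermal(bad2), "block")
})

test_that("block summaries average within individual x block", {
  th <- generate_thermal_cohort(thermal_gen_params(
    n_individuals = 1, proportions = 0.1, body_block_sd = 0, within_block_sd = 0,
    eye_noise_sd = 0, substrate_noise_sd = 0, dl_noise_sd = 0,
    ir_dropouts = 0, dl_zero_readings = 0, seed = 1))$thermal
  bs <- block_summaries(th)
  expect_equal(bs$mean_body_temp, c(25, 20, 15, 20, 25))
  expect_equal(bs$n_points, rep(3, 5))
  expect_equal(attr(bs, "n_dl_invalid"), 0)
})

test_that("heating/cooling rates and their conservation identity", {
  bs <- block_table("a", c(25, 20, 15, 20, 25))
  r <- thermal_rates(bs)
  expect_equal(r$cooling_rate, 10)
  expect_equal(r$heating_rate, 10)
  expect_equal(r$start_end_change, 0)

  bs2 <- block_table("b", c(24.8, 20, 16.0, 20, 24.2))
  r2 <- thermal_rates(bs2)
  expect_equal(r2$cooling_rate, 8.8)
  expect_equal(r2$heating_rate, 8.2)
  expect_equal(r2$start_end_change, r2$heating_rate - r2$cooling_rate)
  expect_equal(r2$log_heating, log(8.2))

  # non-positive rate: flagged and not silently logged
  bs3 <- block_table("c", c(15, 20, 25, 20, 15))
  expect_warning(r3 <- thermal_rates(bs3), "non-positive")
  expect_true(is.na(r3$log_cooling))
  expect_false(r3$rates_positive)

  expect_error(thermal_rates(block_table("d", c(25, 20, 20, 25), blocks = c(1, 2, 4, 5))),
               "missing block 3")
})

test_that("proportion is invariant to image resolution", {
  # same scene rasterized at 1x and 2x: proportions agree within 0.01
  p1 <- generate_image(image_gen_params(target_proportion = 0.2, seed = 6))
  p2 <- generate_image(image_gen_params(width = 320L, height = 240L,
                                        target_proportion = 0.2, seed = 6))
  expect_lt(abs(p1$proportion - 0.2), 0.01)
  expect_lt(abs(p2$proportion - 0.2), 0.01)
  s1 <- segment_pattern(p1$record, seg_config(seed = 1))
  s2 <- segment_pattern(p2$record, seg_config(seed = 1))
  m1 <- pattern_metrics(p1$record, s1)
  m2 <- pattern_metrics(p2$record, s2)
  expect_lt(abs(m1$melanistic_proportion - m2$melanistic_proportion), 0.01)
})
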