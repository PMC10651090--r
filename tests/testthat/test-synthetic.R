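test_that("image generation is deterministic and hits the coverage target", {
  p <- image_gen_params(target_proportion = 0.41, seed = 13)
  a <- generate_image(p)
  b <- generate_image(p)
  expect_identical(a$record$pixels, b$record$pixels)  # bit-identical per seed
  expect_lt(abs(a$proportion - 0.41), 0.01)

  zero <- generate_image(image_gen_params(target_proportion = 0, seed = 1))
  expect_equal(sum(zero$spot_mask), 0)
  expect_equal(zero$proportion, 0)
})

test_that("truth masks and record geometry are mutually consistent", {
  gi <- generate_image(image_gen_params(target_proportion = 0.3, seed = 21))
  expect_true(all(gi$spot_mask[gi$spot_mask] & gi$body_mask[gi$spot_mask]))
  expect_equal(gi$proportion, sum(gi$spot_mask) / sum(gi$body_mask))
  expect_true(all(gi$body_mask[gi$record$roi == FALSE] == FALSE))  # roi covers body
})

test_that("a series keeps one pattern under pose jitter and lighting drift", {
  sr <- generate_image_series(image_gen_params(target_proportion = 0.22, seed = 3),
                              T = 6)
  expect_equal(nrow(sr$truth), 6)
  expect_equal(sr$truth$gain[1], 1)  # nominal baseline frame
  # re-rasterized truth varies only marginally across poses
  expect_lt(diff(range(sr$truth$true_proportion)), 0.02)

  # with unit gains, frames differ only by pose, never by photometry:
  # the reference patch is identical in every frame
  sg <- generate_image_series(image_gen_params(target_proportion = 0.1, seed = 4),
                              T = 3, gains = c(1, 1, 1))
  refs <- vapply(sg$frames, function(f) ref_stats(f$record)$mean_lightness,
                 numeric(1))
  expect_lt(diff(range(refs)), 0.01)
})

test_that("noiseless thermal cohort reproduces the block schedule exactly", {
  p <- thermal_gen_params(n_individuals = 2, proportions = c(0.1, 0.2),
                          body_block_sd = 0, within_block_sd = 0,
                          eye_noise_sd = 0, substrate_noise_sd = 0,
                          dl_noise_sd = 0, lum_noise_sd = 0,
                          ir_dropouts = 0, dl_zero_readings = 0, seed = 2)
  co <- generate_thermal_cohort(p)
  bs <- block_summaries(read_thermal(co$thermal))
  expect_equal(bs$mean_body_temp, rep(c(25, 20, 15, 20, 25), 2))
  r <- thermal_rates(bs)
  expect_equal(r$cooling_rate, c(10, 10))
  expect_equal(r$heating_rate, c(10, 10))
  expect_equal(r$start_end_change, c(0, 0))
})

test_that("injected effects are recovered exactly on noiseless cohorts", {
  p <- thermal_gen_params(body_block_sd = 0.8, within_block_sd = 0,
                          eye_noise_sd = 0, substrate_noise_sd = 0,
                          dl_noise_sd = 0, lum_noise_sd = 0,
                          ir_dropouts = 0, dl_zero_readings = 0,
                          effect_lum_slope = -0.4, effect_interaction = 0.04,
                          seed = 6)
  co <- generate_thermal_cohort(p)
  ind <- co$individuals
  lb <- co$lum_blocks
  dlum <- vapply(split(lb, lb$individual_id), function(g)
    g$mean_lum_nonmel[g$block == 5] - g$mean_lum_nonmel[g$block == 3], numeric(1))
  d <- data.frame(dlum = dlum[ind$individual_id],
                  logp = ind$log_mean_proportion,
                  dT = co$truth$heating_dT)
  fit <- suppressWarnings(ols_fit(dlum ~ logp * dT, d))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est["logp"]), -0.4, tolerance = 1e-8)
  expect_equal(unname(est["logp:dT"]), 0.04, tolerance = 1e-8)
  expect_lt(abs(est["(Intercept)"]), 1e-8)
})

test_that("an extreme responder at high melanism is the one flagged by Cook's distance", {
  # the individual with the largest melanistic proportion (leverage at the
  # extreme of log proportion) is given an aberrant luminance response
  co <- generate_thermal_cohort(thermal_gen_params(
    outlier_individual = 12L, outlier_shift = 0.5, seed = 10))
  rep <- run_analysis(co$thermal, co$lum_blocks, co$individuals)
  model <- rep$models$lum_nonmel_heating
  expect_equal(names(which.max(model$cooks)), "ind12")
  expect_gt(max(model$cooks), 1)
  expect_equal(model$influential, "ind12")
})

test_that("generators are pure functions of (params, seed)", {
  p <- thermal_gen_params(seed = 99)
  expect_identical(generate_thermal_cohort(p), generate_thermal_cohort(p))
  set.seed(123); before <- runif(1)
  invisible(generate_thermal_cohort(p))
  set.seed(123)
  expect_identical(before, runif(1))  # no leakage into the caller's RNG
})
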