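# Synthetic-data generators. They emulate the study's measurement setup --
# a spotted, yellow-based animal photographed on a white arena with an
# in-frame gray standard under drifting illumination, and a 25 -> 15 -> 25
# degrees C five-block thermal protocol -- with exact ground truth, so every
# pipeline stage is testable without the original photographs.

#' Image-generator parameters
#'
#' Describes one synthetic animal: an ellipse-chain body (head, trunk,
#' tapering tail) in a near-black spot pattern on a yellowish base, on a
#' bright white background with a gray reference patch in the top-left
#' corner.
#'
#' @param width,height image size in pixels.
#' @param target_proportion desired melanistic coverage of the body, in
#'   `[0, 0.5]`; realized coverage lands within 0.01 of this.
#' @param base_color,melanistic_color,bg_gray,ref_gray scene colors in
#'   `[0, 1]` (base and spot RGB; background and reference-patch gray
#'   levels).
#' @param ref_rect half-open reference-patch rectangle
#'   `c(row0, col0, row1, col1)`.
#' @param spot_radius_range min/max spot radius in pixels.
#' @param illumination_gain frame lightness multiplier (1 = nominal).
#' @param shadow_amplitude amplitude of a smooth left-right multiplicative
#'   lightness gradient (0 disables).
#' @param noise_sd per-channel Gaussian pixel noise SD.
#' @param scale geometric scale of the animal (2 with doubled width/height =
#'   the same scene photographed at twice the resolution).
#' @param seed integer RNG seed; generation is a pure function of
#'   (params, seed).
#' @return list of class `image_gen_params`.
#' @export
image_gen_params <- function(width = 160L, height = 120L,
                             target_proportion = 0.2,
                             base_color = c(0.78, 0.66, 0.34),
                             melanistic_color = c(0.10, 0.09, 0.08),
                             bg_gray = 0.96, ref_gray = 0.60,
                             ref_rect = c(3L, 3L, 20L, 20L),
                             spot_radius_range = c(2, 5.5),
                             illumination_gain = 1,
                             shadow_amplitude = 0.02,
                             noise_sd = 0.008, scale = 1, seed = 1L) {
  stopifnot(target_proportion >= 0, target_proportion <= 0.5,
            all(base_color >= 0 & base_color <= 1),
            all(melanistic_color >= 0 & melanistic_color <= 1),
            illumination_gain > 0, noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 target_proportion = target_proportion,
                 base_color = base_color, melanistic_color = melanistic_color,
                 bg_gray = bg_gray, ref_gray = ref_gray,
                 ref_rect = as.integer(ref_rect),
                 spot_radius_range = spot_radius_range,
                 illumination_gain = illumination_gain,
                 shadow_amplitude = shadow_amplitude,
                 noise_sd = noise_sd, scale = scale, seed = as.integer(seed)),
            class = "image_gen_params")
}

# Body geometry in a body-centered frame (y = rows, x = cols): trunk ellipse,
# head ellipse to the left, tapering tail cone to the right. Sized for the
# default 160 x 120 canvas with margin for pose jitter.
.body_geom <- function(scale = 1) {
  list(center = c(y = 66, x = 82) * scale,
       trunk = c(a = 17, b = 30) * scale,      # semi-axes (rows, cols)
       head = c(y = 0, x = -44, a = 11, b = 14) * scale,
       tail = c(x0 = 30, x1 = 62, r0 = 9, r1 = 0.8) * scale)
}

# Is a body-frame point inside the body?
.in_body <- function(yb, xb, g) {
  trunk <- (yb / g$trunk["a"])^2 + (xb / g$trunk["b"])^2 <= 1
  head <- ((yb - g$head["y"]) / g$head["a"])^2 +
          ((xb - g$head["x"]) / g$head["b"])^2 <= 1
  u <- (xb - g$tail["x0"]) / (g$tail["x1"] - g$tail["x0"])
  r <- g$tail["r0"] * (1 - u) + g$tail["r1"] * u
  tail <- u >= 0 & u <= 1 & abs(yb) <= r
  trunk | head | tail
}

# Body-frame coordinates of every pixel under a pose (rotation theta in
# degrees, integer-ish translation, mild shear), as two H x W matrices.
.pixel_body_coords <- function(h, w, g, pose) {
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  y <- rowg - g$center["y"] - pose$ty
  x <- colg - g$center["x"] - pose$tx
  th <- pose$theta * pi / 180
  yb <- cos(th) * y - sin(th) * x
  xb <- sin(th) * y + cos(th) * x + pose$shear * yb
  list(yb = yb, xb = xb)
}

.identity_pose <- function() list(theta = 0, tx = 0, ty = 0, shear = 0)

# Place spots (body-frame circles) by dart throwing until the base-pose
# rasterized coverage reaches the target; the last radius is tuned by
# bisection. Returns a data frame of (y, x, r).
.place_spots <- function(params, g, max_spots = 600L) {
  t <- params$target_proportion
  h <- params$height; w <- params$width
  bc <- .pixel_body_coords(h, w, g, .identity_pose())
  body <- .in_body(bc$yb, bc$xb, g)
  n_body <- sum(body)
  spots <- data.frame(y = numeric(0), x = numeric(0), r = numeric(0))
  if (t == 0) return(spots)
  spot_mask <- matrix(FALSE, h, w)
  coverage <- function(extra_mask) sum((spot_mask | extra_mask) & body) / n_body
  render_spot <- function(y, x, r) (bc$yb - y)^2 + (bc$xb - x)^2 <= r^2
  yr <- c(-g$trunk["a"], g$trunk["a"])
  xr <- c(g$head["x"] - g$head["b"], g$tail["x1"])
  for (i in seq_len(max_spots)) {
    repeat {
      sy <- stats::runif(1, yr[1], yr[2])
      sx <- stats::runif(1, xr[1], xr[2])
      if (.in_body(sy, sx, g)) break
    }
    r <- stats::runif(1, params$spot_radius_range[1] * params$scale,
                      params$spot_radius_range[2] * params$scale)
    cov <- coverage(render_spot(sy, sx, r))
    if (cov >= t) {
      # overshoot: shrink this last spot by bisection onto the target
      if (cov > t + 0.005) {
        lo <- 0; hi <- r
        for (b in 1:40) {
          mid <- (lo + hi) / 2
          if (coverage(render_spot(sy, sx, mid)) >= t) hi <- mid else lo <- mid
        }
        r <- hi
      }
      spots <- rbind(spots, data.frame(y = sy, x = sx, r = r))
      spot_mask <- spot_mask | render_spot(sy, sx, r)
      break
    }
    spots <- rbind(spots, data.frame(y = sy, x = sx, r = r))
    spot_mask <- spot_mask | render_spot(sy, sx, r)
  }
  if (coverage(matrix(FALSE, h, w)) < t - 0.01)
    stop("target_proportion ", t, " not attainable with these spot parameters")
  spots
}

# Render one frame of an animal (geometry + spots) under a pose and
# illumination gain. Returns the image_record plus exact truth masks.
.render_frame <- function(params, g, spots, pose, gain, individual_id,
                          seq_index, block) {
  h <- params$height; w <- params$width
  bc <- .pixel_body_coords(h, w, g, pose)
  body <- .in_body(bc$yb, bc$xb, g)
  spot <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(spots)))
    spot <- spot | ((bc$yb - spots$y[i])^2 + (bc$xb - spots$x[i])^2 <= spots$r[i]^2)
  spot <- spot & body
  px <- array(params$bg_gray, c(h, w, 3L))
  for (ch in 1:3) {
    m <- px[, , ch]
    m[body] <- params$base_color[ch]
    m[spot] <- params$melanistic_color[ch]
    px[, , ch] <- m
  }
  r <- params$ref_rect
  px[r[1]:(r[3] - 1), r[2]:(r[4] - 1), ] <- params$ref_gray
  # illumination: multiplicative gain (plus a smooth shadow gradient) on HLS
  # lightness, the channel the camera's exposure drift acts on
  hls <- rgb_to_hls(matrix(px, ncol = 3L))
  grad <- 1 + params$shadow_amplitude *
    (matrix(seq_len(w), h, w, byrow = TRUE) / w - 0.5)
  hls[, 2L] <- pmin(1, hls[, 2L] * gain * as.numeric(grad))
  px <- array(hls_to_rgb(hls), c(h, w, 3L))
  if (params$noise_sd > 0)
    px <- px + stats::rnorm(length(px), 0, params$noise_sd)
  px[px < 0] <- 0; px[px > 1] <- 1
  roi <- .dilate1(.dilate1(.dilate1(body)))
  rec <- image_record(px, individual_id, seq_index, block,
                      ref_region = params$ref_rect, roi = roi)
  list(record = rec, body_mask = body, spot_mask = spot,
       proportion = if (any(body)) sum(spot) / sum(body) else 0)
}

#' Generate one synthetic animal photograph with ground truth
#'
#' Deterministic given `params$seed`. The realized melanistic coverage of
#' the rendered body lands within 0.01 of `target_proportion` (dart-thrown
#' spots; the final spot radius is tuned by bisection).
#'
#' @param params an [image_gen_params()].
#' @param individual_id,seq_index,block metadata for the resulting record.
#' @return list: `record` (an `image_record`), `body_mask`, `spot_mask`
#'   (logical H x W ground truth), `proportion` (realized true coverage).
#' @export
generate_image <- function(params = image_gen_params(), individual_id = "sim1",
                           seq_index = 1L, block = 1L) {
  g <- .body_geom(params$scale)
  .with_seed(params$seed, {
    spots <- .place_spots(params, g)
    .render_frame(params, g, spots, .identity_pose(), params$illumination_gain,
                  individual_id, seq_index, block)
  })
}

#' Generate a photo series of one individual
#'
#' One fixed spot pattern re-posed by mild affine jitter (rotation,
#' translation, shear) across `T` frames with per-frame illumination gains,
#' emulating repeated photographs of the same freely moving animal. The
#' first frame is taken at nominal lighting (gain 1) and serves as the
#' standardization baseline; later frames drift uniformly in
#' `[0.7, 1.3]` by default. Truth masks are re-rasterized per frame, so the
#' recorded true proportion is exact for every frame.
#'
#' @param params an [image_gen_params()].
#' @param T number of frames (>= 2; the study took 15 per individual).
#' @param gains optional length-`T` vector of illumination gains.
#' @param blocks per-frame block labels (default 5 blocks of 3).
#' @param individual_id id stamped on all frames.
#' @return list: `frames` (list of [generate_image()]-style tuples) and
#'   `truth` (data frame of per-frame true proportions).
#' @export
generate_image_series <- function(params = image_gen_params(), T = 15L,
                                  gains = NULL,
                                  blocks = rep(1:5, each = ceiling(T / 5))[seq_len(T)],
                                  individual_id = "sim1") {
  if (T < 2L) stop("T must be >= 2")
  g <- .body_geom(params$scale)
  .with_seed(params$seed, {
    spots <- .place_spots(params, g)
    if (is.null(gains)) gains <- c(1, stats::runif(T - 1L, 0.7, 1.3))
    if (length(gains) != T) stop("gains must have length T")
    frames <- vector("list", T)
    for (t in seq_len(T)) {
      pose <- if (t == 1L) .identity_pose() else
        list(theta = stats::runif(1, -6, 6), tx = stats::runif(1, -4, 4),
             ty = stats::runif(1, -4, 4), shear = stats::runif(1, -0.04, 0.04))
      frames[[t]] <- .render_frame(params, g, spots, pose, gains[t],
                                   individual_id, t, blocks[t])
    }
    truth <- data.frame(individual_id = individual_id, seq_index = seq_len(T),
                        block = blocks, gain = gains,
                        true_proportion = vapply(frames, `[[`, numeric(1), "proportion"),
                        stringsAsFactors = FALSE)
    list(frames = frames, truth = truth)
  })
}

#' Thermal-cohort generator parameters
#'
#' Defaults mirror the study's shape: 12 individuals (7 males, 5 females),
#' 15 timepoints in five blocks of three, a 25 -> 20 -> 15 -> 20 -> 25
#' degrees C block profile, melanistic proportions spanning 0.01--0.41 with
#' nine individuals at or below 0.11, two dropped low-quality IR images,
#' and one zero (invalid) datalogger reading.
#'
#' @param n_individuals cohort size.
#' @param timepoints IR/photo timepoints per individual.
#' @param block_targets target temperature of blocks 1..5 (degrees C).
#' @param blocks per-timepoint block labels.
#' @param body_block_sd SD of per-individual block-mean body temperature
#'   around the target.
#' @param within_block_sd per-timepoint SD around the individual block mean.
#' @param eye_noise_sd per-eye measurement SD (the two eyes are averaged).
#' @param substrate_noise_sd substrate IR reading SD around the body latent.
#' @param dl_offsets named offsets of the cold/warm/hide/atmospheric
#'   dataloggers from the block target.
#' @param dl_noise_sd datalogger reading SD.
#' @param humidity_mean,humidity_sd relative-humidity process (percent).
#' @param proportions per-individual true melanistic proportions.
#' @param n_males number of males (the rest are females).
#' @param svl_mean,svl_sd,mass_mean,mass_sd body-size distributions (mm, g).
#' @param effect_rate_slope injected slope of heating rate on log
#'   proportion (degrees C per log unit; 0 = null world).
#' @param effect_lum_slope injected main-effect slope of the heating-phase
#'   non-melanistic luminance change on log proportion.
#' @param effect_interaction injected coefficient of log proportion x body
#'   temperature change on the same luminance change.
#' @param lum_base_mel,lum_base_nonmel baseline class luminances.
#' @param lum_noise_sd SD of per-block luminance fluctuation.
#' @param ir_dropouts number of individuals losing one random IR timepoint.
#' @param dl_zero_readings number of datalogger records zeroed out
#'   (instrument failure).
#' @param outlier_individual optional index of one individual given an
#'   extreme luminance response (`outlier_shift`), to exercise influence
#'   diagnostics.
#' @param outlier_shift luminance-change shift for that individual.
#' @param seed integer RNG seed.
#' @return list of class `thermal_gen_params`.
#' @export
thermal_gen_params <- function(n_individuals = 12L, timepoints = 15L,
                               block_targets = c(25, 20, 15, 20, 25),
                               blocks = rep(1:5, each = 3L),
                               body_block_sd = 0.8, within_block_sd = 0.2,
                               eye_noise_sd = 0.15, substrate_noise_sd = 0.25,
                               dl_offsets = c(cold = -1, warm = 1.5, hide = 0, atmos = -2.5),
                               dl_noise_sd = 0.3,
                               humidity_mean = 41, humidity_sd = 3,
                               proportions = c(0.01, 0.02, 0.03, 0.04, 0.05, 0.07,
                                               0.08, 0.10, 0.11, 0.16, 0.22, 0.41),
                               n_males = 7L,
                               svl_mean = 125, svl_sd = 8,
                               mass_mean = 55, mass_sd = 8,
                               effect_rate_slope = 0,
                               effect_lum_slope = 0,
                               effect_interaction = 0,
                               lum_base_mel = 0.25, lum_base_nonmel = 0.60,
                               lum_noise_sd = 0.01,
                               ir_dropouts = 2L, dl_zero_readings = 1L,
                               outlier_individual = NULL, outlier_shift = 0,
                               seed = 1L) {
  stopifnot(length(block_targets) == 5L, length(blocks) == timepoints,
            all(blocks %in% 1:5), all(1:5 %in% blocks),
            body_block_sd >= 0, within_block_sd >= 0, eye_noise_sd >= 0,
            lum_noise_sd >= 0, n_individuals >= 1L)
  if (length(proportions) == 1L) proportions <- rep(proportions, n_individuals)
  stopifnot(length(proportions) == n_individuals, all(proportions > 0))
  structure(as.list(environment()), class = "thermal_gen_params")
}

#' Generate a synthetic thermal cohort with ground truth
#'
#' Produces the per-timepoint thermal table consumed by [read_thermal()],
#' per-individual covariates, and per-block class luminances with optional
#' injected effects of melanistic proportion on heating rate and on
#' heating-phase luminance change (main effect and interaction with body
#' temperature change). Deterministic given `params$seed`.
#'
#' @param params a [thermal_gen_params()].
#' @return list: `thermal` (per-timepoint data frame), `individuals`
#'   (covariates + true proportions; columns `mean_proportion` and
#'   `log_mean_proportion` feed the analysis directly), `lum_blocks`
#'   (per individual x block class luminances), `truth` (injected effect
#'   sizes and latent block means).
#' @export
generate_thermal_cohort <- function(params = thermal_gen_params()) {
  p <- params
  .with_seed(p$seed, {
    ids <- sprintf("ind%02d", seq_len(p$n_individuals))
    logp <- log(p$proportions)
    n_m <- min(p$n_males, p$n_individuals)
    sex <- factor(c(rep("M", n_m), rep("F", p$n_individuals - n_m)))
    svl <- stats::rnorm(p$n_individuals, p$svl_mean, p$svl_sd)
    mass <- stats::rnorm(p$n_individuals, p$mass_mean, p$mass_sd)
    # latent per-individual block means; heating injection shifts block 5
    B <- outer(rep(1, p$n_individuals), p$block_targets) +
      matrix(stats::rnorm(p$n_individuals * 5L, 0, p$body_block_sd),
             p$n_individuals, 5L)
    B[, 5L] <- B[, 5L] + p$effect_rate_slope * (logp - mean(logp))
    thermal <- NULL
    for (i in seq_len(p$n_individuals)) {
      bl <- p$blocks
      latent <- B[i, bl] + stats::rnorm(p$timepoints, 0, p$within_block_sd)
      eye_L <- latent + stats::rnorm(p$timepoints, 0, p$eye_noise_sd)
      eye_R <- latent + stats::rnorm(p$timepoints, 0, p$eye_noise_sd)
      snout <- latent + stats::rnorm(p$timepoints, 0, p$eye_noise_sd)
      substrate <- latent + stats::rnorm(p$timepoints, 0, p$substrate_noise_sd)
      df <- data.frame(
        individual_id = ids[i], seq_index = seq_len(p$timepoints), block = bl,
        head = latent + stats::rnorm(p$timepoints, 0.1, p$eye_noise_sd),
        left_knee = latent + stats::rnorm(p$timepoints, -0.2, p$eye_noise_sd),
        left_foot = latent + stats::rnorm(p$timepoints, -0.3, p$eye_noise_sd),
        dorsum = latent + stats::rnorm(p$timepoints, 0, p$eye_noise_sd),
        eye_L = eye_L, eye_R = eye_R, snout = snout,
        tail = latent + stats::rnorm(p$timepoints, -0.4, p$eye_noise_sd),
        substrate_temp = substrate,
        dl_cold = p$block_targets[bl] + p$dl_offsets[["cold"]] +
          stats::rnorm(p$timepoints, 0, p$dl_noise_sd),
        dl_warm = p$block_targets[bl] + p$dl_offsets[["warm"]] +
          stats::rnorm(p$timepoints, 0, p$dl_noise_sd),
        dl_hide = p$block_targets[bl] + p$dl_offsets[["hide"]] +
          stats::rnorm(p$timepoints, 0, p$dl_noise_sd),
        dl_atmos = p$block_targets[bl] + p$dl_offsets[["atmos"]] +
          stats::rnorm(p$timepoints, 0, p$dl_noise_sd),
        humidity = pmin(100, pmax(0, stats::rnorm(p$timepoints, p$humidity_mean,
                                                  p$humidity_sd))),
        stringsAsFactors = FALSE
      )
      thermal <- rbind(thermal, df)
    }
    # low-quality IR images: all IR-derived readings of one timepoint lost
    if (p$ir_dropouts > 0L) {
      for (i in seq_len(min(p$ir_dropouts, p$n_individuals))) {
        tdrop <- sample.int(p$timepoints, 1L)
        row <- thermal$individual_id == ids[i] & thermal$seq_index == tdrop
        thermal[row, c("head", "left_knee", "left_foot", "dorsum", "eye_L",
                       "eye_R", "snout", "tail", "substrate_temp")] <- NA_real_
      }
    }
    # instrument failure: a datalogger reading of exactly zero
    if (p$dl_zero_readings > 0L) {
      zi <- sample.int(nrow(thermal), p$dl_zero_readings)
      thermal$dl_cold[zi] <- 0
    }
    # per-block class luminances with injected heating-phase change
    dT <- B[, 5L] - B[, 3L]
    delta <- p$effect_lum_slope * logp + p$effect_interaction * logp * dT +
      stats::rnorm(p$n_individuals, 0, p$lum_noise_sd)
    if (!is.null(p$outlier_individual))
      delta[p$outlier_individual] <- delta[p$outlier_individual] + p$outlier_shift
    lum_nonmel <- matrix(p$lum_base_nonmel +
                           stats::rnorm(p$n_individuals * 5L, 0, p$lum_noise_sd),
                         p$n_individuals, 5L)
    lum_nonmel[, 5L] <- lum_nonmel[, 3L] + delta
    lum_mel <- matrix(p$lum_base_mel +
                        stats::rnorm(p$n_individuals * 5L, 0, p$lum_noise_sd),
                      p$n_individuals, 5L)
    lum_blocks <- data.frame(
      individual_id = rep(ids, each = 5L),
      block = rep(1:5, p$n_individuals),
      mean_lum_mel = as.numeric(t(lum_mel)),
      mean_lum_nonmel = as.numeric(t(lum_nonmel)),
      stringsAsFactors = FALSE
    )
    individuals <- data.frame(
      individual_id = ids, sex = sex, svl = svl, mass = mass,
      mean_proportion = p$proportions, log_mean_proportion = logp,
      stringsAsFactors = FALSE
    )
    list(thermal = thermal, individuals = individuals, lum_blocks = lum_blocks,
         truth = list(block_means = B, heating_dT = dT, lum_delta = delta,
                      effect_rate_slope = p$effect_rate_slope,
                      effect_lum_slope = p$effect_lum_slope,
                      effect_interaction = p$effect_interaction))
  })
}
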