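# Pattern and thermal quantification: per-image melanistic proportion and
# class-wise luminance, per-individual summaries, eye-averaged body
# temperature, per-block means, and heating/cooling rates.

#' Per-image pattern metrics
#'
#' Melanistic proportion (melanistic area over the whole dorsal foreground)
#' and the mean luminance of the melanistic and non-melanistic areas,
#' computed on the lightness-standardized image. Low-contrast images get
#' proportion 0 and an undefined (`NA`) melanistic luminance.
#'
#' @param img the (standardized) `image_record`.
#' @param seg the matching [segment_pattern()] result; must not be
#'   QC-rejected.
#' @param weights luminance channel weights, see [lum_weights()].
#' @return one-row data frame: `individual_id`, `seq_index`, `block`,
#'   `melanistic_proportion`, `mean_lum_mel`, `mean_lum_nonmel`,
#'   `low_contrast`.
#' @export
pattern_metrics <- function(img, seg, weights = lum_weights()) {
  stopifnot(inherits(img, "image_record"), inherits(seg, "segmentation"))
  if (isFALSE(seg$qc_accepted))
    stop("segmentation was QC-rejected; metrics must not be computed from it")
  fg <- seg$foreground_mask
  if (!any(fg)) stop("empty foreground")
  mel <- seg$melanistic_mask
  lum <- .luminance_matrix(img$pixels, weights)
  prop <- sum(mel) / sum(fg)
  data.frame(
    individual_id = img$individual_id,
    seq_index = img$seq_index,
    block = img$block,
    melanistic_proportion = prop,
    mean_lum_mel = if (any(mel)) mean(lum[mel]) else NA_real_,
    mean_lum_nonmel = mean(lum[fg & !mel]),
    low_contrast = seg$low_contrast,
    stringsAsFactors = FALSE
  )
}

#' Per-individual pattern summary
#'
#' Mean and sample standard deviation of the melanistic proportion over an
#' individual's accepted images, plus the natural log of the mean proportion
#' (the scale the downstream models use). The log is `NA` and flagged when
#' the mean proportion is 0.
#'
#' @param metrics per-image metrics data frame for one individual
#'   ([pattern_metrics()] rows).
#' @return one-row data frame: `individual_id`, `mean_proportion`,
#'   `sd_proportion`, `log_mean_proportion`, `log_defined`, `n_images`.
#' @export
summarize_individual <- function(metrics) {
  if (nrow(metrics) == 0L) stop("no accepted images for this individual")
  id <- unique(metrics$individual_id)
  if (length(id) != 1L) stop("metrics must come from a single individual")
  p <- metrics$melanistic_proportion
  m <- mean(p)
  data.frame(
    individual_id = id,
    mean_proportion = m,
    sd_proportion = if (length(p) > 1L) stats::sd(p) else 0,
    log_mean_proportion = if (m > 0) log(m) else NA_real_,
    log_defined = m > 0,
    n_images = length(p),
    stringsAsFactors = FALSE
  )
}

#' Eye-averaged internal body temperature
#'
#' The internal body temperature proxy is the mean of the left and right eye
#' surface temperatures. If one or both eyes are missing the snout
#' temperature is used instead, with a warning (eye and snout temperatures
#' are very strongly correlated); an error is raised when eyes and snout are
#' all missing.
#'
#' @param part_temps named list or vector of per-body-part temperatures in
#'   degrees C; `eye_L`, `eye_R` and optionally `snout` are used.
#' @return body temperature in degrees C.
#' @export
body_temperature <- function(part_temps) {
  eL <- .num_or_na(part_temps[["eye_L"]])
  eR <- .num_or_na(part_temps[["eye_R"]])
  if (is.finite(eL) && is.finite(eR)) return((eL + eR) / 2)
  sn <- .num_or_na(part_temps[["snout"]])
  if (is.finite(sn)) {
    warning("eye temperature missing; falling back to snout temperature")
    return(sn)
  }
  stop("cannot derive body temperature: both eyes and snout are missing")
}

.num_or_na <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)

#' Read and validate a per-timepoint thermal table
#'
#' Expects columns `individual_id`, `seq_index`, `block`, per-body-part
#' temperatures (`head`, `left_knee`, `left_foot`, `dorsum`, `eye_L`,
#' `eye_R`, `snout`, `tail`), `substrate_temp`, datalogger readings
#' (`dl_cold`, `dl_warm`, `dl_hide`, `dl_atmos`) and `humidity`. Adds a
#' `body_temp` column (eye average with snout fallback; `NA` when a row has
#' no usable reading, e.g. a dropped low-quality IR image), flags datalogger
#' readings of exactly 0 degrees C as invalid (`dl_valid`), and computes the
#' within-terrarium datalogger mean `dl_mean` (`NA` when invalid). Temperatures
#' outside the plausible 0--50 degrees C band raise an error.
#'
#' @param x path to a CSV file or a data frame in that schema.
#' @return validated data frame with `body_temp`, `dl_valid`, `dl_mean`.
#' @export
read_thermal <- function(x) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("individual_id", "seq_index", "block", "eye_L", "eye_R", "snout",
            "substrate_temp", "dl_cold", "dl_warm", "dl_hide", "dl_atmos",
            "humidity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("thermal table missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$block %in% 1:5)) stop("block labels must be integers 1..5")
  temp_cols <- intersect(c("head", "left_knee", "left_foot", "dorsum", "eye_L",
                           "eye_R", "snout", "tail", "substrate_temp",
                           "dl_cold", "dl_warm", "dl_hide", "dl_atmos"), names(df))
  vals <- unlist(df[temp_cols])
  if (any(vals < 0 | vals > 50, na.rm = TRUE))
    stop("temperature outside plausible band [0, 50] degrees C")
  df$body_temp <- vapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    if (!is.finite(.num_or_na(row$eye_L)) && !is.finite(.num_or_na(row$eye_R)) &&
        !is.finite(.num_or_na(row$snout))) return(NA_real_)
    suppressWarnings(body_temperature(as.list(row)))
  }, numeric(1))
  # a datalogger reading of exactly 0 degrees C is an instrument failure
  df$dl_valid <- df$dl_cold != 0 & df$dl_warm != 0 & df$dl_hide != 0
  dlm <- rowMeans(df[, c("dl_cold", "dl_warm", "dl_hide")])
  dlm[!df$dl_valid] <- NA_real_
  df$dl_mean <- dlm
  df
}

#' Per-individual, per-block summaries
#'
#' Mean body temperature (and, when per-image metrics are supplied, mean
#' melanistic and non-melanistic luminance) of each individual in each
#' experimental block. Rows without a usable body temperature (dropped IR
#' images) are excluded; invalid zero datalogger readings are excluded from
#' the datalogger mean and counted. Attributes `n_ir_used`, `n_dl_used` and
#' `n_dl_invalid` carry the filter tallies.
#'
#' @param thermal a [read_thermal()] table.
#' @param metrics optional per-image metrics ([pattern_metrics()] rows,
#'   already QC-filtered) matched on `individual_id` + `seq_index`.
#' @return data frame with one row per individual x block: `mean_body_temp`,
#'   `mean_dl`, `n_points`, and luminance means when available.
#' @export
block_summaries <- function(thermal, metrics = NULL) {
  if (!all(c("body_temp", "dl_valid") %in% names(thermal)))
    thermal <- read_thermal(thermal)
  split_key <- interaction(thermal$individual_id, thermal$block, drop = TRUE)
  rows <- lapply(split(thermal, split_key), function(g) {
    ok <- is.finite(g$body_temp)
    if (!any(ok)) stop("block ", g$block[1L], " of ", g$individual_id[1L],
                       " has no valid body-temperature points")
    data.frame(individual_id = g$individual_id[1L], block = g$block[1L],
               mean_body_temp = mean(g$body_temp[ok]),
               mean_dl = mean(g$dl_mean, na.rm = TRUE),
               n_points = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$individual_id, out$block), ]
  if (!is.null(metrics)) {
    mk <- interaction(metrics$individual_id, metrics$block, drop = TRUE)
    lum <- lapply(split(metrics, mk), function(g) {
      data.frame(individual_id = g$individual_id[1L], block = g$block[1L],
                 mean_lum_mel = mean(g$mean_lum_mel, na.rm = TRUE),
                 mean_lum_nonmel = mean(g$mean_lum_nonmel),
                 stringsAsFactors = FALSE)
    })
    lum <- do.call(rbind, lum)
    out <- merge(out, lum, by = c("individual_id", "block"), all.x = TRUE,
                 sort = FALSE)
    out <- out[order(out$individual_id, out$block), ]
  }
  rownames(out) <- NULL
  attr(out, "n_ir_used") <- sum(is.finite(thermal$body_temp))
  attr(out, "n_dl_used") <- sum(thermal$dl_valid)
  attr(out, "n_dl_invalid") <- sum(!thermal$dl_valid)
  out
}

#' Per-individual heating and cooling rates
#'
#' Rates are block-mean body-temperature differences, oriented so that both
#' are positive under the intended 25 -> 15 -> 25 degrees C profile:
#' cooling = block 1 mean - block 3 mean, heating = block 5 mean - block 3
#' mean, and the start-to-end change = block 5 - block 1 (= heating -
#' cooling by construction). Natural logs are attached for positive rates;
#' non-positive rates get `NA` logs and are flagged, never silently logged.
#'
#' @param summaries a [block_summaries()] table (blocks 1, 3 and 5 required
#'   for every individual).
#' @return data frame with one row per individual: `cooling_rate`,
#'   `heating_rate`, `start_end_change`, `log_cooling`, `log_heating`,
#'   `rates_positive`.
#' @export
thermal_rates <- function(summaries) {
  rows <- lapply(split(summaries, summaries$individual_id), function(g) {
    b <- function(k) {
      i <- which(g$block == k)
      if (length(i) != 1L) stop("individual ", g$individual_id[1L],
                                " is missing block ", k)
      g$mean_body_temp[i]
    }
    cooling <- b(1) - b(3)
    heating <- b(5) - b(3)
    data.frame(individual_id = g$individual_id[1L],
               cooling_rate = cooling, heating_rate = heating,
               start_end_change = b(5) - b(1),
               log_cooling = if (cooling > 0) log(cooling) else NA_real_,
               log_heating = if (heating > 0) log(heating) else NA_real_,
               rates_positive = cooling > 0 && heating > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(!out$rates_positive))
    warning("non-positive heating/cooling rate for: ",
            paste(out$individual_id[!out$rates_positive], collapse = ", "),
            " (excluded from log-scale models)")
  out
}
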