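# End-to-end image pipeline: standardize a series against its first frame's
# grayscale reference, segment every frame, and tabulate metrics; plus
# manifest-driven file I/O and a one-call synthetic study writer.

#' Process one individual's photo series
#'
#' Standardizes every frame's lightness against the grayscale reference of
#' the first frame (by `seq_index`), segments the melanistic pattern, and
#' computes per-image metrics.
#'
#' @param records list of `image_record`s of one individual.
#' @param cfg a [seg_config()].
#' @param weights luminance weights.
#' @return list: `metrics` (data frame, one row per frame), `segmentations`
#'   (list), `baseline` (the `ref_stats` used).
#' @export
process_series <- function(records, cfg = seg_config(), weights = lum_weights()) {
  ids <- unique(vapply(records, `[[`, character(1), "individual_id"))
  if (length(ids) != 1L)
    stop("process_series expects frames of a single individual, got: ",
         paste(ids, collapse = ", "))
  ord <- order(vapply(records, `[[`, integer(1), "seq_index"))
  records <- records[ord]
  baseline <- ref_stats(records[[1L]])
  segs <- vector("list", length(records))
  metrics <- vector("list", length(records))
  for (i in seq_along(records)) {
    std <- standardize_lightness(records[[i]], baseline)
    segs[[i]] <- segment_pattern(std, cfg)
    metrics[[i]] <- pattern_metrics(std, segs[[i]], weights)
  }
  list(metrics = do.call(rbind, metrics), segmentations = segs,
       baseline = baseline)
}

#' Read an experiment manifest
#'
#' The manifest CSV lists one row per photograph: `individual_id`,
#' `seq_index`, `block`, `image_path`, `ref_row0`, `ref_col0`, `ref_row1`,
#' `ref_col1` (half-open reference rectangle) and `roi_path` (a 0/255
#' single-channel PNG mask). Paths are resolved relative to the manifest's
#' directory.
#'
#' @param path manifest CSV path.
#' @return data frame with resolved paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "seq_index", "block", "image_path",
            "ref_row0", "ref_col0", "ref_row1", "ref_col1", "roi_path")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  base <- dirname(path)
  man$image_path <- file.path(base, man$image_path)
  man$roi_path <- file.path(base, man$roi_path)
  man
}

#' Run the full extraction pipeline over a manifest
#'
#' Loads every image and its ROI mask, then runs [process_series()] per
#' individual. Optionally writes QC overlays.
#'
#' @param manifest a [read_manifest()] data frame or a path to one.
#' @param cfg a [seg_config()].
#' @param qc_dir if non-NULL, QC overlays and a flag file are written here.
#' @return list: `metrics` (all individuals), `segmentations` (named by
#'   individual).
#' @export
process_manifest <- function(manifest, cfg = seg_config(), qc_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  out_metrics <- list(); out_segs <- list()
  for (id in unique(manifest$individual_id)) {
    rows <- manifest[manifest$individual_id == id, ]
    records <- lapply(seq_len(nrow(rows)), function(i) {
      roi <- png::readPNG(rows$roi_path[i])
      if (length(dim(roi)) == 3L) roi <- roi[, , 1L]
      read_image(rows$image_path[i],
                 ref_region = as.integer(rows[i, c("ref_row0", "ref_col0",
                                                   "ref_row1", "ref_col1")]),
                 roi = roi > 0.5,
                 individual_id = id, seq_index = rows$seq_index[i],
                 block = rows$block[i])
    })
    res <- process_series(records, cfg)
    if (!is.null(qc_dir)) {
      dir.create(qc_dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_along(records))
        qc_overlay(records[[i]], res$segmentations[[i]],
                   file.path(qc_dir, sprintf("%s_%02d.png", id,
                                             records[[i]]$seq_index)),
                   file.path(qc_dir, "qc_flags.csv"))
    }
    out_metrics[[id]] <- res$metrics
    out_segs[[id]] <- res$segmentations
  }
  list(metrics = do.call(rbind, c(out_metrics, make.row.names = FALSE)),
       segmentations = out_segs)
}

#' Write a complete ready-to-run synthetic study to disk
#'
#' Generates a photo series per individual (spot coverage equal to the
#' cohort's true proportions) and a matching thermal cohort, and writes
#' images, ROI masks, a manifest, thermal and individual CSVs, and a truth
#' table. This is the dataset layout [process_manifest()] and
#' [run_analysis()] consume.
#'
#' @param dir output directory.
#' @param params a [thermal_gen_params()]; image seeds and per-individual
#'   spot targets derive from it.
#' @param image_params base [image_gen_params()] (per-individual target
#'   proportion and seed are overridden).
#' @param T frames per individual.
#' @return `dir`, invisibly; side effect: files under `dir`.
#' @export
simulate_study <- function(dir, params = thermal_gen_params(),
                           image_params = image_gen_params(), T = params$timepoints) {
  dir.create(file.path(dir, "images"), showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_thermal_cohort(params)
  man <- NULL; truth <- NULL
  for (i in seq_len(params$n_individuals)) {
    id <- cohort$individuals$individual_id[i]
    ip <- image_params
    ip$target_proportion <- min(params$proportions[i], 0.5)
    ip$seed <- params$seed * 1000L + i
    series <- generate_image_series(ip, T = T, blocks = params$blocks,
                                    individual_id = id)
    for (t in seq_len(T)) {
      img_file <- sprintf("images/%s_%02d.png", id, t)
      roi_file <- sprintf("images/%s_%02d_roi.png", id, t)
      fr <- series$frames[[t]]
      write_image_png(fr$record, file.path(dir, img_file))
      png::writePNG(fr$record$roi * 1, target = file.path(dir, roi_file))
      man <- rbind(man, data.frame(
        individual_id = id, seq_index = t, block = params$blocks[t],
        image_path = img_file,
        ref_row0 = ip$ref_rect[1], ref_col0 = ip$ref_rect[2],
        ref_row1 = ip$ref_rect[3], ref_col1 = ip$ref_rect[4],
        roi_path = roi_file, stringsAsFactors = FALSE))
    }
    truth <- rbind(truth, series$truth)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$thermal, file.path(dir, "thermal.csv"), row.names = FALSE)
  utils::write.csv(cohort$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(dir, "image_truth.csv"), row.names = FALSE)
  utils::write.csv(cohort$lum_blocks, file.path(dir, "lum_blocks_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
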