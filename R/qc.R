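# Quality-control artifacts. The unsupervised clustering is known to fail on
# shadowed regions, so every segmentation gets a reviewable overlay plus a
# recorded accept/reject flag; rejected images are excluded downstream and
# the exclusions are counted, keeping the decision auditable and the pipeline
# scriptable (no blocking interactive step).

#' Write a QC overlay and register a review flag
#'
#' Writes a side-by-side PNG (original | original with the melanistic mask
#' tinted red and the foreground outline in blue) and appends a `pending` row
#' to the flag file for later acceptance or rejection with [qc_set_flag()].
#'
#' @param img the `image_record` that was segmented.
#' @param seg the corresponding [segment_pattern()] result.
#' @param out_path path for the overlay PNG.
#' @param flag_path path of the CSV flag file (created if missing).
#' @return `out_path`, invisibly.
#' @export
qc_overlay <- function(img, seg, out_path, flag_path = file.path(dirname(out_path), "qc_flags.csv")) {
  stopifnot(inherits(img, "image_record"), inherits(seg, "segmentation"))
  left <- img$pixels
  right <- img$pixels
  mel <- seg$melanistic_mask
  right[, , 1L][mel] <- pmin(1, 0.6 + 0.4 * right[, , 1L][mel])
  right[, , 2L][mel] <- 0.3 * right[, , 2L][mel]
  right[, , 3L][mel] <- 0.3 * right[, , 3L][mel]
  edge <- seg$foreground_mask & !.erode1(seg$foreground_mask)
  right[, , 1L][edge] <- 0.1
  right[, , 2L][edge] <- 0.3
  right[, , 3L][edge] <- 1
  d <- dim(left)
  combined <- array(0, c(d[1L], 2L * d[2L] + 2L, 3L))
  combined[, seq_len(d[2L]), ] <- left
  combined[, d[2L] + 3L:(d[2L] + 2L), ] <- right
  png::writePNG(combined, target = out_path)
  row <- data.frame(individual_id = img$individual_id,
                    seq_index = img$seq_index, block = img$block,
                    status = "pending", overlay = out_path,
                    stringsAsFactors = FALSE)
  utils::write.table(row, flag_path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(flag_path), append = file.exists(flag_path))
  invisible(out_path)
}

.erode1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  out[2:h, ] <- out[2:h, ] & mask[1:(h - 1), ]
  out[1:(h - 1), ] <- out[1:(h - 1), ] & mask[2:h, ]
  out[, 2:w] <- out[, 2:w] & mask[, 1:(w - 1)]
  out[, 1:(w - 1)] <- out[, 1:(w - 1)] & mask[, 2:w]
  out
}

.dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  out[2:h, ] <- out[2:h, ] | mask[1:(h - 1), ]
  out[1:(h - 1), ] <- out[1:(h - 1), ] | mask[2:h, ]
  out[, 2:w] <- out[, 2:w] | mask[, 1:(w - 1)]
  out[, 1:(w - 1)] <- out[, 1:(w - 1)] | mask[, 2:w]
  out
}

#' Record a QC decision
#'
#' @param flag_path CSV flag file written by [qc_overlay()].
#' @param individual_id,seq_index identify the image.
#' @param status `"accepted"` or `"rejected"`.
#' @return the updated flag table, invisibly.
#' @export
qc_set_flag <- function(flag_path, individual_id, seq_index, status) {
  status <- match.arg(status, c("accepted", "rejected", "pending"))
  flags <- utils::read.csv(flag_path, stringsAsFactors = FALSE)
  hit <- flags$individual_id == individual_id & flags$seq_index == seq_index
  if (!any(hit)) stop("no QC record for ", individual_id, " #", seq_index)
  flags$status[hit] <- status
  utils::write.csv(flags, flag_path, row.names = FALSE)
  invisible(flags)
}

#' Apply QC decisions to a metrics table
#'
#' Drops rows flagged `rejected`; anything not explicitly rejected (accepted
#' or still pending) is retained. The number of exclusions is recorded in the
#' `n_rejected` attribute.
#'
#' @param metrics a per-image metrics data frame with `individual_id` and
#'   `seq_index` columns.
#' @param flags flag data frame (or path to the flag CSV).
#' @return filtered data frame with attribute `n_rejected`.
#' @export
qc_filter <- function(metrics, flags) {
  if (is.character(flags)) flags <- utils::read.csv(flags, stringsAsFactors = FALSE)
  key <- paste(metrics$individual_id, metrics$seq_index)
  bad <- paste(flags$individual_id[flags$status == "rejected"],
               flags$seq_index[flags$status == "rejected"])
  keep <- !(key %in% bad)
  out <- metrics[keep, , drop = FALSE]
  attr(out, "n_rejected") <- sum(!keep)
  out
}
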