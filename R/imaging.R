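# Image records: one timestamped RGB photograph of one individual, with the
# geometry of its grayscale reference patch and dorsal region of interest.

#' Construct an image record
#'
#' Bundles one RGB photograph of one individual with its grayscale-reference
#' rectangle and dorsal region of interest (ROI). Pixel values must lie in
#' `[0, 1]`. Rectangles are 1-based and half-open: `c(row0, col0, row1, col1)`
#' covers rows `row0 .. row1 - 1` and columns `col0 .. col1 - 1`.
#'
#' @param pixels H x W x 3 numeric array with values in `[0, 1]`.
#' @param individual_id character scalar identifying the animal.
#' @param seq_index integer position of this photograph in the individual's
#'   time series (1-based).
#' @param block experimental block label (integer 1..5).
#' @param ref_region integer vector `c(row0, col0, row1, col1)`, half-open,
#'   delimiting the grayscale reference patch.
#' @param roi region of interest delimiting head + trunk + tail: either a
#'   logical H x W matrix or a polygon (two-column matrix/data frame of
#'   `(row, col)` vertices, converted with [polygon_mask()]).
#' @param sat_threshold raw-lightness level at or above which a pixel is
#'   flagged as saturated at capture (no usable color information); such
#'   pixels are excluded from the animal foreground downstream.
#' @return an object of class `image_record`.
#' @export
image_record <- function(pixels, individual_id, seq_index = 1L, block = 1L,
                         ref_region, roi, sat_threshold = 0.98) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L)
    stop("'pixels' must be an H x W x 3 array")
  if (any(!is.finite(pixels))) stop("'pixels' contains non-finite values")
  if (any(pixels < 0 | pixels > 1)) stop("'pixels' values must lie in [0, 1]")
  h <- dim(pixels)[1L]; w <- dim(pixels)[2L]
  ref_region <- as.integer(ref_region)
  .check_rect(ref_region, h, w)
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == c(h, w))) stop("'roi' mask must match image dimensions")
  } else {
    roi <- polygon_mask(roi, h, w)
  }
  if (!any(roi)) stop("'roi' is empty")
  ref_mask <- matrix(FALSE, h, w)
  ref_mask[ref_region[1L]:(ref_region[3L] - 1L),
           ref_region[2L]:(ref_region[4L] - 1L)] <- TRUE
  if (any(roi & ref_mask))
    stop("'roi' and 'ref_region' overlap; the reference patch must lie outside the animal ROI")
  structure(list(
    pixels = pixels,
    individual_id = as.character(individual_id),
    seq_index = as.integer(seq_index),
    block = as.integer(block),
    ref_region = ref_region,
    roi = roi,
    saturated = .lightness_matrix(pixels) >= sat_threshold,
    standardized = FALSE
  ), class = "image_record")
}

.check_rect <- function(rect, h, w) {
  if (length(rect) != 4L || any(!is.finite(rect)))
    stop("rectangle must be c(row0, col0, row1, col1)")
  if (rect[1L] < 1L || rect[2L] < 1L || rect[3L] > h + 1L || rect[4L] > w + 1L)
    stop("rectangle exceeds image bounds")
  if (rect[3L] <= rect[1L] || rect[4L] <= rect[2L])
    stop("rectangle is empty (half-open: row1 > row0 and col1 > col0 required)")
  invisible(rect)
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_record> %s #%d (block %d): %d x %d px, roi %d px, ref %s%s\n",
              x$individual_id, x$seq_index, x$block, d[1L], d[2L], sum(x$roi),
              paste(x$ref_region, collapse = ","),
              if (isTRUE(x$standardized)) ", lightness-standardized" else ""))
  invisible(x)
}

#' Rasterize a polygon ROI to a logical mask
#'
#' @param vertices two-column matrix or data frame of `(row, col)` polygon
#'   vertices (pixel coordinates, need not be closed).
#' @param h,w image dimensions.
#' @return logical `h` x `w` matrix, `TRUE` for pixel centers inside the
#'   polygon.
#' @export
polygon_mask <- function(vertices, h, w) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L)
    stop("'roi' polygon needs a two-column matrix of at least 3 (row, col) vertices")
  if (any(v[, 1L] < 1 | v[, 1L] > h | v[, 2L] < 1 | v[, 2L] > w))
    stop("'roi' polygon exceeds image bounds")
  pts <- cbind(rep(seq_len(h), times = w), rep(seq_len(w), each = h))
  inside <- mgcv::in.out(rbind(v, v[1L, , drop = FALSE]), pts)
  matrix(inside, h, w)
}

#' Read a photograph into an image record
#'
#' Reads an 8-bit (or 16-bit) RGB image, scales channels to `[0, 1]`
#' (dividing by 255 or 65535 as appropriate -- handled by the decoders), and
#' attaches reference-patch and ROI geometry. PNG and TIFF are read natively;
#' JPEG requires the EBImage package.
#'
#' @inheritParams image_record
#' @param path path to a PNG/TIFF/JPEG file.
#' @return an `image_record`.
#' @export
read_image <- function(path, ref_region, roi, individual_id = "ind1",
                       seq_index = 1L, block = 1L, sat_threshold = 0.98) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG input requires the EBImage package")
      img <- EBImage::readImage(path)
      aperm(EBImage::imageData(img), c(2L, 1L, 3L))
    },
    stop("unsupported image format: .", ext)
  )
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))  # grayscale
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]        # drop alpha
  image_record(px, individual_id, seq_index, block, ref_region, roi,
               sat_threshold = sat_threshold)
}

#' Write an image record (or raw array) as PNG
#'
#' @param x an `image_record` or H x W x 3 array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  px <- if (inherits(x, "image_record")) x$pixels else x
  png::writePNG(px, target = path)
  invisible(path)
}

#' Grayscale-reference statistics
#'
#' Mean HLS lightness of the in-frame grayscale reference patch. The patch in
#' an individual's first photograph serves as the baseline that later frames
#' of the same individual are standardized against.
#'
#' @param img an `image_record`.
#' @return an object of class `ref_stats`: `mean_lightness`, `n_pixels`, and
#'   the source `individual_id`.
#' @export
ref_stats <- function(img) {
  stopifnot(inherits(img, "image_record"))
  r <- img$ref_region
  L <- .lightness_matrix(img$pixels)[r[1L]:(r[3L] - 1L), r[2L]:(r[4L] - 1L)]
  if (length(L) == 0L) stop("reference region is empty")
  structure(list(mean_lightness = mean(L), n_pixels = length(L),
                 individual_id = img$individual_id),
            class = "ref_stats")
}

#' @export
print.ref_stats <- function(x, ...) {
  cat(sprintf("<ref_stats> %s: mean lightness %.4f over %d px\n",
              x$individual_id, x$mean_lightness, x$n_pixels))
  invisible(x)
}

#' Standardize image lightness against a baseline grayscale reference
#'
#' Multiplies every pixel's HLS lightness by the gain
#' `g = baseline mean / current reference mean`, clips to `[0, 1]`, and
#' converts back to RGB. After standardization the reference patch of every
#' frame matches the first frame's patch, cancelling multiplicative
#' illumination drift, so luminance is comparable across frames of the same
#' individual -- but not across individuals, which is refused unless
#' `allow_cross_individual = TRUE`.
#'
#' @param img an `image_record`.
#' @param baseline a `ref_stats` object, normally from the same individual's
#'   first photograph.
#' @param allow_cross_individual override the within-individual guard.
#' @return the standardized `image_record`, with attributes `gain` (the
#'   applied multiplier) and `n_clipped` (pixels whose lightness clipped at 1).
#' @export
standardize_lightness <- function(img, baseline, allow_cross_individual = FALSE) {
  stopifnot(inherits(img, "image_record"), inherits(baseline, "ref_stats"))
  if (!allow_cross_individual &&
      !identical(baseline$individual_id, img$individual_id))
    stop("baseline comes from individual '", baseline$individual_id,
         "' but image is of '", img$individual_id,
         "'; lightness standardization is within-individual ",
         "(set allow_cross_individual = TRUE to override)")
  if (!is.finite(baseline$mean_lightness) || baseline$mean_lightness <= 0)
    stop("baseline mean lightness must be positive")
  cur <- ref_stats(img)
  if (cur$mean_lightness < 1e-6)
    stop("current reference patch is black (mean lightness ~0); gain undefined")
  g <- baseline$mean_lightness / cur$mean_lightness
  d <- dim(img$pixels)
  hls <- rgb_to_hls(matrix(img$pixels, ncol = 3L))
  Lg <- hls[, 2L] * g
  n_clipped <- sum(Lg > 1)
  hls[, 2L] <- pmin(Lg, 1)
  out <- img
  out$pixels <- array(hls_to_rgb(hls), d)
  out$standardized <- TRUE
  attr(out, "gain") <- g
  attr(out, "n_clipped") <- n_clipped
  out
}
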