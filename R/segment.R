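# Melanistic-pattern segmentation: background exclusion, k-means++ seeding,
# Lloyd's algorithm with an explicit empty-cluster rule, and bisecting
# (hierarchical) recursion. Every pixel is a point in RGB space; with the
# default k = 2 the darker cluster is the stable melanistic pattern.

#' Segmentation configuration
#'
#' @param k clusters per split (default 2: melanistic vs non-melanistic).
#' @param max_depth bisecting recursion depth. Depth 1 with `k = 2` is the
#'   default; deeper values refine within-class structure but the
#'   melanistic/non-melanistic call is always made at the top split, keeping a
#'   conservative melanin estimate.
#' @param tol convergence tolerance on the maximum center movement, in `[0,1]`
#'   RGB units.
#' @param max_iter Lloyd iteration cap.
#' @param seed integer RNG seed; segmentation is deterministic given
#'   (image, config, seed).
#' @param bg_lightness_threshold pixels with standardized lightness at or
#'   above this are treated as white background, not animal.
#' @param contrast_threshold minimum luminance difference between the two
#'   top-level cluster centers for a pattern to be called; below it the image
#'   is flagged low-contrast and the melanistic proportion is 0 (patternless
#'   individuals are a real part of the study population).
#' @param n_restarts independent k-means++ restarts; the run with the lowest
#'   inertia wins. Default 1.
#' @return a list of class `seg_config`.
#' @export
seg_config <- function(k = 2L, max_depth = 1L, tol = 1e-4, max_iter = 100L,
                       seed = 1L, bg_lightness_threshold = 0.92,
                       contrast_threshold = 10 / 255, n_restarts = 1L) {
  stopifnot(k >= 2L, max_depth >= 1L, tol > 0, max_iter >= 1L, n_restarts >= 1L,
            bg_lightness_threshold >= 0, bg_lightness_threshold <= 1,
            contrast_threshold >= 0, contrast_threshold <= 1)
  structure(list(k = as.integer(k), max_depth = as.integer(max_depth),
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed),
                 bg_lightness_threshold = bg_lightness_threshold,
                 contrast_threshold = contrast_threshold,
                 n_restarts = as.integer(n_restarts)),
            class = "seg_config")
}

# Run code with a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Animal foreground within the ROI
#'
#' Pixels inside the ROI whose (standardized) lightness falls below the
#' white-background threshold and that were not saturated at capture.
#'
#' @param img an `image_record` (normally lightness-standardized).
#' @param cfg a [seg_config()].
#' @return logical H x W mask.
#' @export
foreground_mask <- function(img, cfg = seg_config()) {
  stopifnot(inherits(img, "image_record"))
  L <- .lightness_matrix(img$pixels)
  fg <- img$roi & (L < cfg$bg_lightness_threshold) & !img$saturated
  if (!any(fg))
    stop("no animal foreground found in ROI (all pixels background-bright or saturated)")
  fg
}

#' k-means++ center initialization
#'
#' The first center is drawn uniformly at random; each subsequent center is
#' drawn with probability proportional to the squared distance to its nearest
#' already-chosen center. This makes the clustering robust to its
#' initialization, which plain k-means is sensitive to.
#'
#' @param pixels N x 3 numeric matrix (or N x d generally).
#' @param k number of centers.
#' @param seed integer RNG seed; the draw is deterministic given the seed.
#' @return k x d matrix of initial centers.
#' @export
kmeanspp_init <- function(pixels, k, seed = 1L) {
  pixels <- as.matrix(pixels)
  n <- nrow(pixels)
  if (nrow(unique(pixels)) < k)
    stop("fewer than k distinct pixels; cannot place ", k, " centers")
  .with_seed(seed, {
    centers <- matrix(NA_real_, k, ncol(pixels))
    idx <- sample.int(n, 1L)
    centers[1L, ] <- pixels[idx, ]
    d2 <- rowSums((pixels - rep(centers[1L, ], each = n))^2)
    for (j in seq_len(k - 1L) + 1L) {
      idx <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- pixels[idx, ]
      d2 <- pmin(d2, rowSums((pixels - rep(centers[j, ], each = n))^2))
    }
    centers
  })
}

#' Lloyd's k-means from given initial centers
#'
#' Alternates nearest-center assignment and center-mean updates until the
#' maximum center movement drops below `tol` or `max_iter` is reached. The
#' within-cluster sum of squares (inertia) is recorded after every assignment
#' step and checked to be non-increasing. A cluster left empty by an
#' assignment step is re-seeded at the point currently farthest from its
#' assigned center.
#'
#' @param pixels N x d numeric matrix.
#' @param centers initial k x d centers.
#' @param tol convergence tolerance on maximum center movement.
#' @param max_iter iteration cap.
#' @return list with `centers`, `labels` (length-N integer), `inertia`,
#'   `n_iter`, and `inertia_history`.
#' @export
kmeans_lloyd <- function(pixels, centers, tol = 1e-4, max_iter = 100L) {
  pixels <- as.matrix(pixels)
  centers <- as.matrix(centers)
  stopifnot(ncol(pixels) == ncol(centers), tol > 0)
  n <- nrow(pixels); k <- nrow(centers)
  history <- numeric(0L)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(pixels, centers)
    labels <- max.col(-d2, ties.method = "first")
    point_d2 <- d2[cbind(seq_len(n), labels)]
    # empty-cluster rule: re-seed at the point farthest from its center
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        far <- which.max(point_d2)
        centers[j, ] <- pixels[far, ]
        labels[far] <- j
        point_d2[far] <- 0
      }
    }
    inertia <- sum(point_d2)
    if (length(history) && inertia > history[length(history)] + 1e-9)
      stop("internal error: inertia increased during Lloyd iteration")
    history <- c(history, inertia)
    new_centers <- centers
    for (j in seq_len(k))
      new_centers[j, ] <- colMeans(pixels[labels == j, , drop = FALSE])
    movement <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (movement < tol) break
  }
  # final assignment against the converged centers
  d2 <- .dist2(pixels, centers)
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), labels)])
  list(centers = centers, labels = labels, inertia = inertia,
       n_iter = it, inertia_history = history)
}

.dist2 <- function(x, centers) {
  # N x k matrix of squared Euclidean distances
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

#' Segment the melanistic pattern of one photograph
#'
#' Runs background exclusion, k-means++ initialization, and (bisecting)
#' k-means on the foreground pixels in RGB space. The top-level cluster whose
#' center has the lower luminance is labelled melanistic. If the two top-level
#' centers differ in luminance by less than `contrast_threshold` the image is
#' flagged `low_contrast` and the melanistic mask is empty (proportion 0):
#' individuals with essentially no pattern are reported as such rather than
#' split arbitrarily. With `max_depth > 1` each side is recursively bisected
#' for refined sub-cluster centers; the class call still comes from the top
#' split.
#'
#' @param img an `image_record`, normally lightness-standardized first.
#' @param cfg a [seg_config()].
#' @return an object of class `segmentation`: `melanistic_mask`,
#'   `foreground_mask` (logical H x W), `centers`, `labels` (per foreground
#'   pixel), `inertia`, `low_contrast`, `qc_accepted` (NA until reviewed),
#'   `leaves` (bisecting sub-clusters when `max_depth > 1`), and image
#'   metadata.
#' @export
segment_pattern <- function(img, cfg = seg_config()) {
  stopifnot(inherits(img, "image_record"))
  fg <- foreground_mask(img, cfg)
  px <- cbind(img$pixels[, , 1L][fg], img$pixels[, , 2L][fg], img$pixels[, , 3L][fg])
  h <- dim(img$pixels)[1L]; w <- dim(img$pixels)[2L]
  res <- list(foreground_mask = fg, individual_id = img$individual_id,
              seq_index = img$seq_index, block = img$block,
              seed = cfg$seed, qc_accepted = NA)
  if (nrow(unique(px)) < cfg$k) {
    # uniform foreground: no pattern to split
    res$centers <- matrix(colMeans(px), 1L)
    res$labels <- rep(1L, nrow(px))
    res$inertia <- 0
    res$low_contrast <- TRUE
    res$melanistic_mask <- matrix(FALSE, h, w)
    class(res) <- "segmentation"
    return(res)
  }
  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    init <- kmeanspp_init(px, cfg$k, seed = cfg$seed + r - 1L)
    fit <- kmeans_lloyd(px, init, tol = cfg$tol, max_iter = cfg$max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  lum <- as.numeric(luminance(best$centers))
  dark <- which.min(lum)
  light <- which.max(lum)
  res$centers <- best$centers
  res$labels <- best$labels
  res$inertia <- best$inertia
  res$low_contrast <- (lum[light] - lum[dark]) < cfg$contrast_threshold
  mel <- matrix(FALSE, h, w)
  if (!res$low_contrast) mel[fg] <- best$labels == dark
  res$melanistic_mask <- mel
  if (cfg$max_depth > 1L && !res$low_contrast) {
    res$leaves <- lapply(seq_len(cfg$k), function(j) {
      .bisect(px[best$labels == j, , drop = FALSE], cfg, depth = cfg$max_depth - 1L,
              seed = cfg$seed + 100L * j)
    })
  }
  class(res) <- "segmentation"
  res
}

# Recursive bisection of a pixel set; returns a list of leaf centers.
.bisect <- function(px, cfg, depth, seed) {
  if (depth == 0L || nrow(unique(px)) < 2L)
    return(list(centers = matrix(colMeans(px), 1L), n = nrow(px)))
  init <- kmeanspp_init(px, 2L, seed = seed)
  fit <- kmeans_lloyd(px, init, tol = cfg$tol, max_iter = cfg$max_iter)
  list(
    .bisect(px[fit$labels == 1L, , drop = FALSE], cfg, depth - 1L, seed + 1L),
    .bisect(px[fit$labels == 2L, , drop = FALSE], cfg, depth - 1L, seed + 2L)
  )
}

#' @export
print.segmentation <- function(x, ...) {
  n_fg <- sum(x$foreground_mask)
  cat(sprintf("<segmentation> %s #%d (block %d): %d foreground px, ",
              x$individual_id, x$seq_index, x$block, n_fg))
  if (x$low_contrast) {
    cat("LOW CONTRAST (no melanistic pattern called)\n")
  } else {
    cat(sprintf("melanistic %.1f%% (inertia %.3f)\n",
                100 * sum(x$melanistic_mask) / n_fg, x$inertia))
  }
  invisible(x)
}
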