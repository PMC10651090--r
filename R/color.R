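# Color-space primitives: hexcone HLS conversion and weighted RGB luminance.
# All channel values live in [0,1]; hue is in degrees [0, 360).

.as_rgb_matrix <- function(rgb, arg = "rgb") {
  if (is.null(dim(rgb))) {
    if (length(rgb) %% 3L != 0L)
      stop(sprintf("'%s' must have length a multiple of 3", arg))
    rgb <- matrix(rgb, ncol = 3L, byrow = TRUE)
  }
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3L) stop(sprintf("'%s' must have 3 columns (R, G, B)", arg))
  if (any(!is.finite(rgb))) stop(sprintf("'%s' contains non-finite values", arg))
  if (any(rgb < 0 | rgb > 1)) stop(sprintf("'%s' components must lie in [0, 1]", arg))
  rgb
}

#' Convert RGB to HLS (hexcone model)
#'
#' Standard hexcone Hue-Lightness-Saturation conversion: `L = (max + min) / 2`,
#' `S = (max - min) / (1 - |2L - 1|)` for chromatic pixels (0 for achromatic
#' ones, where hue is 0 by convention), and hue by hexagonal sector. Used to
#' express photographs in a space where illumination acts on a single channel
#' (lightness), so that frames of one individual can be standardized against
#' its grayscale reference patch.
#'
#' @param rgb numeric vector of length 3, or an N x 3 matrix, of RGB values in
#'   `[0, 1]`.
#' @return For a length-3 vector, a named numeric vector `c(H, L, S)`; for a
#'   matrix, an N x 3 matrix with columns `H`, `L`, `S`. `H` is in degrees
#'   `[0, 360)`; `L` and `S` in `[0, 1]`.
#' @seealso [hls_to_rgb()], [luminance()]
#' @examples
#' rgb_to_hls(c(1, 0, 0))      # pure red: H = 0, L = 0.5, S = 1
#' rgb_to_hls(c(0.2, 0.4, 0.6))
#' @export
rgb_to_hls <- function(rgb) {
  vec <- is.null(dim(rgb)) && length(rgb) == 3L
  m <- .as_rgb_matrix(rgb)
  r <- m[, 1L]; g <- m[, 2L]; b <- m[, 3L]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  L <- (mx + mn) / 2
  S <- numeric(length(L))
  chrom <- d > 0
  # clamp: S is mathematically <= 1, but the denominator cancels
  # catastrophically for near-extreme lightness and can overshoot by ~1e-9
  S[chrom] <- pmin(d[chrom] / (1 - abs(2 * L[chrom] - 1)), 1)
  H <- numeric(length(L))
  i <- chrom & mx == r
  H[i] <- ((g[i] - b[i]) / d[i]) %% 6
  i <- chrom & mx != r & mx == g
  H[i] <- (b[i] - r[i]) / d[i] + 2
  i <- chrom & mx != r & mx != g
  H[i] <- (r[i] - g[i]) / d[i] + 4
  H <- (H * 60) %% 360
  out <- cbind(H = H, L = L, S = S)
  if (vec) out[1L, ] else out
}

#' Convert HLS back to RGB
#'
#' Inverse of [rgb_to_hls()] on its range; the round trip is exact to well
#' below 1e-9.
#'
#' @param hls numeric vector `c(H, L, S)` (H in degrees `[0, 360)`, L and S in
#'   `[0, 1]`) or an N x 3 matrix of such rows.
#' @return RGB values in `[0, 1]`, same shape convention as the input.
#' @export
hls_to_rgb <- function(hls) {
  vec <- is.null(dim(hls)) && length(hls) == 3L
  if (is.null(dim(hls))) {
    if (length(hls) %% 3L != 0L) stop("'hls' must have length a multiple of 3")
    hls <- matrix(hls, ncol = 3L, byrow = TRUE)
  }
  hls <- as.matrix(hls)
  if (ncol(hls) != 3L) stop("'hls' must have 3 columns (H, L, S)")
  H <- hls[, 1L]; L <- hls[, 2L]; S <- hls[, 3L]
  if (any(!is.finite(hls))) stop("'hls' contains non-finite values")
  if (any(H < 0 | H >= 360)) stop("hue must lie in [0, 360)")
  # tolerate float-level overshoot from upstream conversions
  eps <- 1e-9
  if (any(L < -eps | L > 1 + eps | S < -eps | S > 1 + eps))
    stop("L and S must lie in [0, 1]")
  L <- pmin(pmax(L, 0), 1)
  S <- pmin(pmax(S, 0), 1)
  C <- (1 - abs(2 * L - 1)) * S
  Hp <- H / 60
  X <- C * (1 - abs(Hp %% 2 - 1))
  m <- L - C / 2
  r <- g <- b <- numeric(length(H))
  sector <- floor(Hp) %% 6
  i <- sector == 0; r[i] <- C[i]; g[i] <- X[i]
  i <- sector == 1; r[i] <- X[i]; g[i] <- C[i]
  i <- sector == 2; g[i] <- C[i]; b[i] <- X[i]
  i <- sector == 3; g[i] <- X[i]; b[i] <- C[i]
  i <- sector == 4; r[i] <- X[i]; b[i] <- C[i]
  i <- sector == 5; r[i] <- C[i]; b[i] <- X[i]
  out <- cbind(R = r + m, G = g + m, B = b + m)
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (vec) out[1L, ] else out
}

#' Default luminance weights (Rec. 601)
#'
#' The weighted-RGB luminance used as the photometric brightness proxy.
#' Defaults to ITU-R Rec. 601 (0.299, 0.587, 0.114); pass Rec. 709 weights
#' (0.2126, 0.7152, 0.0722) to any function taking a `weights` argument to
#' switch convention.
#'
#' @return named numeric vector of three weights summing to 1.
#' @export
lum_weights <- function() c(R = 0.299, G = 0.587, B = 0.114)

#' Weighted RGB luminance
#'
#' Luminance is the brightness proxy tracked over time: its change in the
#' melanistic and non-melanistic body areas measures physiological color
#' change (melanosome movement within melanophores).
#'
#' @param rgb length-3 RGB vector or N x 3 matrix, values in `[0, 1]`.
#' @param weights channel weights, non-negative, summing to 1.
#' @return scalar (or vector for matrix input) in `[0, 1]`.
#' @export
luminance <- function(rgb, weights = lum_weights()) {
  if (length(weights) != 3L || any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be 3 non-negative values summing to 1")
  m <- .as_rgb_matrix(rgb)
  out <- drop(m %*% as.numeric(weights))
  unname(out)
}

# Lightness (HLS L) of an H x W x 3 array, returned as an H x W matrix.
.lightness_matrix <- function(pixels) {
  (pmax(pixels[, , 1L], pixels[, , 2L], pixels[, , 3L]) +
     pmin(pixels[, , 1L], pixels[, , 2L], pixels[, , 3L])) / 2
}

# Luminance of an H x W x 3 array as an H x W matrix.
.luminance_matrix <- function(pixels, weights = lum_weights()) {
  weights[1L] * pixels[, , 1L] + weights[2L] * pixels[, , 2L] +
    weights[3L] * pixels[, , 3L]
}
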