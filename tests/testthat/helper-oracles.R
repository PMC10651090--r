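# Independent oracles used to pin expected values: brute-force enumeration,
# leave-one-out refits, and exhaustive partition search. These deliberately
# avoid the code paths they check.

# Exact two-sided signed-rank p by enumeration over all 2^n sign vectors
# (tie-free, non-zero differences only).
enum_wilcoxon_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(Vs <= v), mean(Vs >= v)))
}

enum_wilcoxon_v <- function(d) {
  r <- rank(abs(d))
  sum(r[d > 0])
}

# Cook's distance by its definition: squared standardized shift of the fitted
# values when observation i is refit out.
loo_cooks <- function(fit) {
  X <- stats::model.matrix(fit)
  y <- stats::fitted(fit) + stats::residuals(fit)
  p <- ncol(X)
  s2 <- summary(fit)$sigma^2
  vapply(seq_len(nrow(X)), function(i) {
    beta_i <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])$coefficients
    sum((stats::fitted(fit) - as.numeric(X %*% beta_i))^2) / (p * s2)
  }, numeric(1))
}

# Optimal 2-partition of 1-D data by squared-error: exhaustive over all
# contiguous splits of the sorted values (the optimum is always contiguous).
best_2partition_inertia <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  for (i in seq_len(n - 1L)) {
    a <- xs[seq_len(i)]
    b <- xs[(i + 1L):n]
    v <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (v < best) best <- v
  }
  best
}

# Small flat test image: uniform color with optional patches.
flat_image <- function(h, w, color = c(0.5, 0.5, 0.5)) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- color[ch]
  px
}

# A simple two-tone animal record: dark left half, light right half of the
# ROI, on a white background, gray reference patch top-left.
two_tone_record <- function(h = 40, w = 60, dark = c(0.1, 0.1, 0.1),
                            light = c(0.9, 0.8, 0.3)) {
  px <- flat_image(h, w, c(0.98, 0.98, 0.98))
  roi <- matrix(FALSE, h, w)
  roi[15:34, 21:50] <- TRUE
  for (ch in 1:3) {
    m <- px[, , ch]
    m[15:34, 21:35] <- dark[ch]
    m[15:34, 36:50] <- light[ch]
    px[, , ch] <- m
  }
  px[2:9, 2:9, ] <- 0.6
  image_record(px, "t1", 1, 1, ref_region = c(2, 2, 10, 10), roi = roi)
}

# Minimal block-summary table for rate arithmetic tests.
block_table <- function(id, means, blocks = seq_along(means)) {
  data.frame(individual_id = id, block = blocks, mean_body_temp = means,
             mean_dl = means, n_points = 3, stringsAsFactors = FALSE)
}
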