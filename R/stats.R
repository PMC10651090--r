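# The statistical battery: correlations, normality-gated paired block
# contrasts, OLS models with interactions, and Cook's-distance influence
# diagnostics. Standard tests are delegated to base R (cor.test, t.test,
# wilcox.test, shapiro.test, lm); Cook's distance is computed from its
# closed form. All tests are two-sided and uncorrected.

#' Pearson correlation
#'
#' Product-moment correlation with its t-based two-sided p-value. Both `r`
#' and `r_squared` are reported explicitly (and adjusted R-squared is
#' available from [ols_fit()]); the three are distinct quantities and are
#' never conflated.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return list: `r`, `r_squared`, `p`, `n`, `df`.
#' @export
cor_pearson <- function(x, y) {
  .check_cor_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x), df = unname(ct$parameter))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; ties are handled by averaging ranks and
#' the p-value falls back to the t approximation when ties preclude the
#' exact null distribution.
#'
#' @inheritParams cor_pearson
#' @return list: `rho`, `p`, `n`.
#' @export
cor_spearman <- function(x, y) {
  .check_cor_input(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

.check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input: correlation undefined")
  invisible(TRUE)
}

#' Shapiro-Wilk normality check
#'
#' Used only as the alpha = 0.05 gate that chooses between the paired t-test
#' and the Wilcoxon signed-rank test in [paired_contrast()].
#'
#' @param d numeric vector, 3 <= n <= 5000, non-constant.
#' @return list: `W`, `p`, `n`.
#' @export
shapiro_wilk <- function(d) {
  if (length(d) < 3L || length(d) > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (any(!is.finite(d))) stop("input must be finite")
  if (stats::sd(d) == 0) stop("constant input: normality test undefined")
  sw <- stats::shapiro.test(d)
  list(W = unname(sw$statistic), p = sw$p.value, n = length(d))
}

.paired_result <- function(kind, statistic, p, n, normality_p = NA_real_) {
  structure(list(test_kind = kind, statistic = unname(statistic),
                 p = p, n = n, normality_p = normality_p),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  lab <- if (x$test_kind == "t") sprintf("paired t-test: t = %.4g", x$statistic)
         else sprintf("Wilcoxon signed-rank test: V = %g", x$statistic)
  cat(sprintf("%s, n = %d, two-sided p = %.4g", lab, x$n, x$p))
  if (is.finite(x$normality_p))
    cat(sprintf("  [normality gate p = %.3g]", x$normality_p))
  cat("\n")
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' `V` is the sum of the ranks of the positive differences `x - y`, with
#' zero differences dropped and mid-ranks for tied absolute differences. The
#' two-sided p-value is exact (enumeration) for tie-free samples up to
#' moderate n and a continuity-corrected normal approximation otherwise --
#' the standard R conventions.
#'
#' @param x,y paired numeric vectors.
#' @return a `paired_test` result (`test_kind = "wilcoxon"`).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) < 2L) stop("fewer than 2 non-zero differences")
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  .paired_result("wilcoxon", wt$statistic, wt$p.value, length(d))
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors; the differences must have positive
#'   standard deviation.
#' @return a `paired_test` result (`test_kind = "t"`).
#' @export
paired_t <- function(x, y) {
  d <- x - y
  if (length(d) < 2L) stop("need at least 2 pairs")
  if (stats::sd(d) == 0) stop("zero-variance differences: t-test undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  .paired_result("t", tt$statistic, tt$p.value, length(d))
}

#' Normality-gated paired contrast
#'
#' Shapiro-Wilk is run on the paired differences; if its p-value is at or
#' above `alpha` the paired t-test is used, otherwise the Wilcoxon
#' signed-rank test. The gate's p-value is recorded in the result.
#'
#' @param x,y paired numeric vectors.
#' @param alpha normality-gate level (default 0.05).
#' @return a `paired_test` result with `normality_p` filled in.
#' @export
paired_contrast <- function(x, y, alpha = 0.05) {
  d <- x - y
  if (length(d) < 3L) stop("need at least 3 pairs for the normality gate")
  if (stats::sd(d) == 0) stop("zero-variance differences")
  gate <- shapiro_wilk(d)
  res <- if (gate$p >= alpha) paired_t(x, y) else wilcoxon_signed_rank(x, y)
  res$normality_p <- gate$p
  res
}

#' Ordinary least squares fit with influence diagnostics
#'
#' Wraps a least-squares fit of an R model formula (supporting main effects,
#' interactions, and treatment-coded factors such as sex) and attaches the
#' diagnostics the downstream analysis needs: per-term t and two-sided p,
#' adjusted R-squared (which may legitimately be negative), leverages,
#' Cook's distances, and the observations flagged as influential
#' (Cook's distance > 1).
#'
#' @param formula model formula.
#' @param data data frame; rows with missing values in the model variables
#'   are dropped.
#' @return object of class `pattern_lm`: `fit` (the underlying `lm`),
#'   `coefficients` (term/estimate/t/p table), `adj_r_squared`, `residuals`,
#'   `leverages`, `cooks`, `influential` (row labels with D > 1), `n`.
#' @export
ols_fit <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  X <- stats::model.matrix(fit)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than model terms")
  if (fit$rank < ncol(X)) stop("rank-deficient design matrix")
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1L],
                      t = sm$coefficients[, 3L],
                      p = sm$coefficients[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  h <- stats::hatvalues(fit)
  D <- .cooks_formula(stats::residuals(fit), h, p, sm$sigma^2,
                      max(abs(stats::fitted(fit))))
  structure(list(fit = fit, coefficients = coefs,
                 adj_r_squared = sm$adj.r.squared,
                 r_squared = sm$r.squared,
                 residuals = stats::residuals(fit),
                 leverages = h, cooks = D,
                 influential = names(D)[is.finite(D) & D > 1],
                 n = n, p_terms = p),
            class = "pattern_lm")
}

.cooks_formula <- function(e, h, p, s2, fitted_scale = 1) {
  # a numerically perfect fit moves nothing when a point is deleted
  if (s2 <= (1e-10 * (1 + fitted_scale))^2) return(e * 0)
  D <- e^2 * h / (p * s2 * (1 - h)^2)
  D[h >= 1 - 1e-12] <- Inf  # exact-fit point: influence undefined/unbounded
  D
}

#' Cook's distances of a fitted model
#'
#' `D_i = e_i^2 h_ii / (p s^2 (1 - h_ii)^2)`, the squared standardized
#' change in the fitted values when observation i is deleted; observations
#' with `D > 1` are flagged as exerting undue leverage on the fit.
#'
#' @param model a [ols_fit()] result (or an `lm`).
#' @return named numeric vector of Cook's distances.
#' @export
cooks_distance <- function(model) {
  if (inherits(model, "pattern_lm")) return(model$cooks)
  if (inherits(model, "lm")) {
    sm <- summary(model)
    return(.cooks_formula(stats::residuals(model), stats::hatvalues(model),
                          model$rank, sm$sigma^2,
                          max(abs(stats::fitted(model)))))
  }
  stop("'model' must be a pattern_lm or lm object")
}

#' @export
print.pattern_lm <- function(x, digits = 4, ...) {
  cat("<pattern_lm> ", deparse(stats::formula(x$fit)), "\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat(sprintf("n = %d, adjusted R^2 = %.3f", x$n, x$adj_r_squared))
  if (length(x$influential))
    cat("; influential (Cook's D > 1): ", paste(x$influential, collapse = ", "))
  cat("\n")
  invisible(x)
}
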