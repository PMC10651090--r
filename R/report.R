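# Full statistical battery over a prepared dataset: correlations between
# body and environmental temperatures, block contrasts for body temperature
# and class luminance, and the linear-model suite with influence flags.

#' Run the complete block-based thermoregulation analysis
#'
#' Takes a per-timepoint thermal table, per-individual-per-block class
#' luminances, and per-individual covariates (including the mean and
#' log-mean melanistic proportion), and emits every analysis the workflow
#' defines:
#' \itemize{
#'  \item Pearson correlations of body temperature with substrate (IR),
#'    within-terrarium datalogger mean, atmospheric datalogger, and relative
#'    humidity, plus datalogger mean vs IR substrate.
#'  \item Normality-gated paired contrasts (blocks 1-3 cooling, 3-5 heating,
#'    1-5 start/end) for body temperature and for melanistic and
#'    non-melanistic luminance.
#'  \item Linear models: log heating/cooling rate on mass, SVL and sex; log
#'    proportion on SVL x sex; log rates on log proportion; and luminance
#'    change on log proportion x body-temperature change, per class and per
#'    block pair, with Cook's-distance influence flags.
#' }
#'
#' @param thermal per-timepoint thermal table ([read_thermal()] schema).
#' @param lum_blocks data frame `individual_id`, `block`, `mean_lum_mel`,
#'   `mean_lum_nonmel` (from [block_summaries()] on image metrics, or from
#'   the cohort generator).
#' @param individuals data frame with `individual_id`, `sex`, `svl`, `mass`,
#'   `mean_proportion`, `log_mean_proportion`.
#' @param alpha significance level used for the normality gate and for
#'   flagging models whose diagnostics are reported (default 0.05).
#' @return object of class `melano_report`: `correlations` (data frame),
#'   `contrasts` (data frame of `paired_test` summaries), `models` (named
#'   list of `pattern_lm`), `rates`, `block_summaries`, `counts`,
#'   `influential`.
#' @export
run_analysis <- function(thermal, lum_blocks, individuals, alpha = 0.05) {
  need <- c("individual_id", "sex", "svl", "mass", "mean_proportion",
            "log_mean_proportion")
  miss <- setdiff(need, names(individuals))
  if (length(miss)) stop("'individuals' missing columns: ", paste(miss, collapse = ", "))
  thermal <- read_thermal(thermal)
  bs <- block_summaries(thermal)
  filter_counts <- c(n_ir_used = attr(bs, "n_ir_used"),
                     n_dl_used = attr(bs, "n_dl_used"),
                     n_dl_invalid = attr(bs, "n_dl_invalid"))
  bs <- merge(bs, lum_blocks, by = c("individual_id", "block"), all.x = TRUE)
  bs <- bs[order(bs$individual_id, bs$block), ]
  if (!all(c(1, 3, 5) %in% bs$block)) stop("blocks 1, 3 and 5 are required")

  # --- correlations (per-timepoint, complete pairs only) ------------------
  corr_pair <- function(label, x, y) {
    ok <- is.finite(x) & is.finite(y)
    ct <- cor_pearson(x[ok], y[ok])
    data.frame(comparison = label, r = ct$r, r_squared = ct$r_squared,
               p = ct$p, n = ct$n, stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    corr_pair("body_vs_substrate", thermal$body_temp, thermal$substrate_temp),
    corr_pair("body_vs_datalogger", thermal$body_temp, thermal$dl_mean),
    corr_pair("body_vs_atmospheric", thermal$body_temp, thermal$dl_atmos),
    corr_pair("datalogger_vs_substrate", thermal$dl_mean, thermal$substrate_temp),
    corr_pair("body_vs_humidity", thermal$body_temp, thermal$humidity)
  )

  # --- block contrasts ----------------------------------------------------
  wide <- function(var) {
    m <- matrix(NA_real_, length(unique(bs$individual_id)), 5L,
                dimnames = list(sort(unique(bs$individual_id)), NULL))
    m[cbind(match(bs$individual_id, rownames(m)), bs$block)] <- bs[[var]]
    m
  }
  bt <- wide("mean_body_temp")
  lm_mel <- wide("mean_lum_mel")
  lm_non <- wide("mean_lum_nonmel")
  pairs <- list(cooling = c(1, 3), heating = c(3, 5), start_end = c(1, 5))
  contrast_row <- function(var_label, m, phase, blocks) {
    x <- m[, blocks[1L]]; y <- m[, blocks[2L]]
    ok <- is.finite(x) & is.finite(y)
    ct <- paired_contrast(x[ok], y[ok], alpha = alpha)
    data.frame(variable = var_label, phase = phase,
               blocks = paste(blocks, collapse = "-"),
               test = ct$test_kind, statistic = ct$statistic, p = ct$p,
               n = ct$n, normality_p = ct$normality_p, stringsAsFactors = FALSE)
  }
  contrasts <- NULL
  for (ph in names(pairs)) {
    contrasts <- rbind(contrasts,
      contrast_row("body_temp", bt, ph, pairs[[ph]]),
      contrast_row("lum_mel", lm_mel, ph, pairs[[ph]]),
      contrast_row("lum_nonmel", lm_non, ph, pairs[[ph]]))
  }

  # --- per-individual rates and model table -------------------------------
  rates <- thermal_rates(bs)
  tab <- merge(rates, individuals, by = "individual_id")
  tab <- tab[order(tab$individual_id), ]
  for (ph in names(pairs)) {
    b <- pairs[[ph]]
    idx <- match(tab$individual_id, rownames(bt))
    tab[[paste0("dtemp_", ph)]] <- bt[idx, b[2L]] - bt[idx, b[1L]]
    tab[[paste0("dlum_mel_", ph)]] <- lm_mel[idx, b[2L]] - lm_mel[idx, b[1L]]
    tab[[paste0("dlum_nonmel_", ph)]] <- lm_non[idx, b[2L]] - lm_non[idx, b[1L]]
  }

  rownames(tab) <- tab$individual_id  # so influence flags name individuals
  models <- list()
  loggable <- tab[tab$rates_positive, ]
  for (rv in c("log_heating", "log_cooling")) {
    for (pred in c("mass", "svl", "sex")) {
      models[[paste0(rv, "_", pred)]] <-
        ols_fit(stats::as.formula(paste(rv, "~", pred)), loggable)
    }
    models[[paste0(rv, "_proportion")]] <-
      ols_fit(stats::as.formula(paste(rv, "~ log_mean_proportion")), loggable)
  }
  models$proportion_svl_sex <- ols_fit(log_mean_proportion ~ svl * sex, tab)
  for (cls in c("mel", "nonmel")) {
    for (ph in names(pairs)) {
      f <- stats::as.formula(sprintf(
        "dlum_%s_%s ~ log_mean_proportion * dtemp_%s", cls, ph, ph))
      models[[sprintf("lum_%s_%s", cls, ph)]] <- ols_fit(f, tab)
    }
  }
  influential <- lapply(models, function(m) m$influential)
  influential <- influential[vapply(influential, length, integer(1)) > 0L]

  counts <- c(n_individuals = nrow(individuals), filter_counts)

  structure(list(correlations = correlations, contrasts = contrasts,
                 models = models, rates = rates, block_summaries = bs,
                 table = tab, counts = counts, influential = influential,
                 alpha = alpha),
            class = "melano_report")
}

#' @export
print.melano_report <- function(x, ...) {
  cat("== Thermoregulation / melanistic-pattern analysis ==\n")
  cat(sprintf("Individuals: %d | IR points used: %d | datalogger points used: %d (%d invalid)\n\n",
              x$counts["n_individuals"], x$counts["n_ir_used"],
              x$counts["n_dl_used"], x$counts["n_dl_invalid"]))
  cat("-- Temperature correlations --\n")
  print(format(x$correlations, digits = 3), row.names = FALSE)
  cat("\n-- Block contrasts --\n")
  print(format(x$contrasts, digits = 3), row.names = FALSE)
  cat("\n-- Models --\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    sig <- m$coefficients$p[-1L] < x$alpha
    cat(sprintf("  %-28s adjR2 %6.3f%s\n", nm, m$adj_r_squared,
                if (any(sig)) paste0("  [significant terms: ",
                  paste(m$coefficients$term[-1L][sig], collapse = ", "), "]") else ""))
  }
  if (length(x$influential)) {
    cat("\n-- Influential individuals (Cook's D > 1) --\n")
    for (nm in names(x$influential))
      cat(sprintf("  %s: %s\n", nm, paste(x$influential[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Write a report's tables to disk
#'
#' CSV tables (correlations, contrasts, per-model coefficient tables, rates,
#' block summaries) plus a plain-text summary.
#'
#' @param report a [run_analysis()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$rates, file.path(dir, "rates.csv"), row.names = FALSE)
  utils::write.csv(report$block_summaries, file.path(dir, "block_summaries.csv"),
                   row.names = FALSE)
  coefs <- do.call(rbind, lapply(names(report$models), function(nm) {
    cbind(model = nm, report$models[[nm]]$coefficients,
          adj_r_squared = report$models[[nm]]$adj_r_squared)
  }))
  utils::write.csv(coefs, file.path(dir, "model_coefficients.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  invisible(dir)
}
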