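## Agreement between algorithm-measured and manually counted RR: the metric
## suite (MAE, MAPE, RMSE, identity-line R^2, Pearson r, sigma/SD/SEM),
## Bland-Altman limits of agreement, and the age-trend regression.

#' Convert a manual breath count to Hz
#'
#' A complete thoracodorsal/tail undulation counts as 1 breath; a partial
#' cycle counts as 0.5. The count over the observation window divided by the
#' window length gives RR in Hz.
#'
#' @param full_cycles non-negative count of complete cycles (vectorized).
#' @param partial 0 or 0.5 per observation.
#' @param window_s observation window length in seconds (default 10).
#' @return RR in Hz.
#' @export
counts_to_hz <- function(full_cycles, partial = 0, window_s = 10) {
  if (any(full_cycles < 0) || any(partial < 0))
    rr_abort("counts must be non-negative", "rr_validation_error")
  if (!all(partial %in% c(0, 0.5)))
    rr_abort("partial must be 0 or 0.5", "rr_validation_error")
  if (window_s <= 0) rr_abort("window_s must be > 0", "rr_validation_error")
  (full_cycles + partial) / window_s
}

#' Read a manual-counts CSV and average observers
#'
#' Expected columns: `id,observer,window_start_s,full_cycles,partial`.
#' Counts are converted to Hz per row and averaged over observers (and
#' repeated windows) per subject id.
#'
#' @param path CSV path.
#' @param window_s counting window in seconds.
#' @return data.frame with columns `id`, `y_manual` (Hz).
#' @export
load_manual_counts <- function(path, window_s = 10) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "observer", "full_cycles", "partial")
  missing <- setdiff(need, names(rows))
  if (length(missing))
    rr_abort(sprintf("counts file lacks columns: %s",
                     paste(missing, collapse = ", ")), "rr_parse_error")
  rows$hz <- counts_to_hz(rows$full_cycles, rows$partial, window_s)
  agg <- stats::aggregate(hz ~ id, data = rows, FUN = mean)
  names(agg) <- c("id", "y_manual")
  agg
}

#' Pair manual and algorithm measurements
#'
#' @param y_manual manual reference RR values in Hz.
#' @param x_algo algorithm-measured RR values in Hz, same length.
#' @param id optional identifiers.
#' @param age_days,stage,heat_delta optional covariates.
#' @return data.frame of class `paired_measurements`.
#' @export
paired_measurements <- function(y_manual, x_algo, id = seq_along(y_manual),
                                age_days = NA, stage = NA, heat_delta = NA) {
  if (length(y_manual) != length(x_algo))
    rr_abort("y_manual and x_algo must have equal length", "rr_validation_error")
  if (!all(is.finite(y_manual)) || !all(is.finite(x_algo)))
    rr_abort("measurements must be finite", "rr_validation_error")
  structure(data.frame(id = id, y_manual = y_manual, x_algo = x_algo,
                       age_days = age_days, stage = stage,
                       heat_delta = heat_delta),
            class = c("paired_measurements", "data.frame"))
}

#' Agreement metrics between algorithm and manual RR
#'
#' Implements each formula as conventionally printed for this comparison:
#' MAE `= mean|y - x|`; MAPE `= mean|y - x| / y * 100`; RMSE
#' `= sqrt(mean (y - x)^2)`; the coefficient of determination is measured
#' against the identity line, `R^2 = 1 - sum((y - x)^2) / sum((y - ybar)^2)`
#' — not a regression R^2, so a constant offset between methods lowers it
#' even at Pearson r = 1. Dispersion of the manual reference: population
#' sigma (n denominator), sample SD (n - 1), SEM = SD / sqrt(n).
#' Bland-Altman: bias = mean(algorithm - manual), limits of agreement
#' bias +/- 1.96 * SD of the differences.
#'
#' @param pairs a [paired_measurements()] (n >= 2; all `y > 0` for MAPE).
#' @return An object of class `eval_report` with fields `mae`, `mape`,
#'   `rmse`, `r2`, `pearson_r`, `sigma`, `sd`, `sem`, `bias`, `loa_low`,
#'   `loa_high`, `n`.
#' @export
compute_metrics <- function(pairs) {
  y <- pairs$y_manual; x <- pairs$x_algo; n <- length(y)
  if (n < 2L)
    rr_abort("need at least 2 paired measurements", "rr_insufficient_data_error")
  if (any(y == 0))
    rr_abort("MAPE undefined: a manual value is zero", "rr_division_domain_error")
  err <- y - x
  ybar <- mean(y)
  sigma <- sqrt(sum((y - ybar)^2) / n)
  sd_y <- sqrt(sum((y - ybar)^2) / (n - 1))
  d <- x - y                                           # algorithm - manual
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(list(
    mae = mean(abs(err)),
    mape = mean(abs(err) / y) * 100,
    rmse = sqrt(mean(err^2)),
    r2 = 1 - sum(err^2) / sum((y - ybar)^2),
    pearson_r = stats::cor(x, y),
    sigma = sigma, sd = sd_y, sem = sd_y / sqrt(n),
    bias = bias, loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
    n = n), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report: n = %d>\n",
                     "  MAE  %.4f Hz   MAPE %.3f %%   RMSE %.4f Hz\n",
                     "  R2 (identity) %.4f   Pearson r %.4f\n",
                     "  bias %+.5f Hz   LoA [%.4f, %.4f] Hz\n"),
              x$n, x$mae, x$mape, x$rmse, x$r2, x$pearson_r,
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Linear age trend of RR
#'
#' Ordinary least squares of RR (Hz) on age (days). The reported `fit_r2`
#' is the regression coefficient of determination, distinct from the
#' identity-line R^2 of [compute_metrics()].
#'
#' @param ages ages in days (>= 3 distinct values for a trustworthy fit;
#'   exactly 2 distinct values fit perfectly and raise an
#'   under-determination warning).
#' @param rr RR values in Hz, same length.
#' @return `list(slope, intercept, fit_r2)` (slope in Hz/day).
#' @export
fit_linear_trend <- function(ages, rr) {
  if (length(ages) != length(rr))
    rr_abort("ages and rr must have equal length", "rr_validation_error")
  nd <- length(unique(ages))
  if (nd < 2L)
    rr_abort("all ages identical: trend is undefined", "rr_degenerate_design_error")
  if (nd == 2L)
    rr_warn("only 2 distinct ages: linear fit is under-determined",
            "rr_underdetermined_fit")
  fit <- stats::lm(rr ~ ages)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit_r2 = summary(fit)$r.squared)
}

#' Bland-Altman plot (base graphics helper)
#' @param pairs a [paired_measurements()].
#' @param report optional precomputed [compute_metrics()] result.
#' @export
plot_bland_altman <- function(pairs, report = compute_metrics(pairs)) {
  m <- (pairs$x_algo + pairs$y_manual) / 2
  d <- pairs$x_algo - pairs$y_manual
  graphics::plot(m, d, xlab = "mean of methods (Hz)",
                 ylab = "algorithm - manual (Hz)",
                 main = "Bland-Altman agreement", pch = 19)
  graphics::abline(h = c(report$bias, report$loa_low, report$loa_high),
                   lty = c(1, 2, 2))
  invisible(report)
}

#' Identity-line scatter of algorithm vs manual RR (base graphics helper)
#' @param pairs a [paired_measurements()].
#' @export
plot_agreement_scatter <- function(pairs) {
  rng <- range(c(pairs$x_algo, pairs$y_manual))
  graphics::plot(pairs$y_manual, pairs$x_algo, xlim = rng, ylim = rng,
                 xlab = "manual RR (Hz)", ylab = "algorithm RR (Hz)",
                 main = "Agreement with manual counts", pch = 19)
  graphics::abline(0, 1, lty = 2)
  invisible(pairs)
}
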