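#' Descriptive summary of a numeric series
#'
#' Mean, sample SD (n - 1 denominator), minimum, maximum and the t-based 95%
#' confidence interval of the mean, `mean +/- t(0.975, n-1) * SD / sqrt(n)`.
#'
#' @param series Numeric vector, `n >= 2`, no missing values.
#' @return A tibble with columns `n`, `mean`, `sd`, `min`, `max`,
#'   `ci_low`, `ci_high`.
#' @examples
#' descriptive_summary(c(1, 2, 3))
#' @export
descriptive_summary <- function(series) {
  stopifnot(is.numeric(series))
  if (anyNA(series)) stop("series contains missing values; filter explicitly",
                          call. = FALSE)
  n <- length(series)
  if (n < 2L) stop("insufficient data: need n >= 2, got n = ", n,
                   call. = FALSE)
  m <- mean(series)
  s <- stats::sd(series)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  tibble::tibble(n = n, mean = m, sd = s, min = min(series),
                 max = max(series), ci_low = m - half, ci_high = m + half)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' `CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (n-denominator) moments, per Lin's original definition. The 95% CI is
#' computed on Fisher's z scale with the asymptotic standard error of the
#' z-transformed CCC.
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`; at least one must have
#'   non-zero variance (two constant series have no defined concordance).
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return A tibble with `ccc`, `ci_low`, `ci_high`, `n`.
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4)) # ccc = 4/7
#' @export
lin_ccc <- function(x, y, conf_level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values; filter explicitly",
                                 call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("insufficient data: need n >= 2", call. = FALSE)
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  denom <- sx2 + sy2 + (mean(x) - mean(y))^2
  if (denom == 0) {
    stop("concordance undefined: both series constant with equal means",
         call. = FALSE)
  }
  ccc <- 2 * sxy / denom
  # Fisher-z CI (Lin 1989); degenerate when |ccc| = 1 or a series is constant
  ci <- c(NA_real_, NA_real_)
  if (sx2 > 0 && sy2 > 0 && abs(ccc) < 1) {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mean(x) - mean(y)) / (sx2 * sy2)^0.25
    z <- atanh(ccc)
    se_z <- sqrt(
      ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
         2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
         ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2))
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(z + c(-1, 1) * q * se_z)
  }
  tibble::tibble(ccc = ccc, ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Intraclass correlation coefficient (two-way, absolute agreement, single)
#'
#' Reliability of repeated measurements from the standard two-way ANOVA
#' mean-square decomposition of a complete subjects x measurements matrix:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`, the
#' absolute-agreement, single-measure form (appropriate for one rater
#' measuring every subject k times). Degenerate matrices (no between-subject
#' variance) are reported as computed, possibly `<= 0`, never clamped.
#'
#' @param ratings Numeric matrix, subjects in rows (`n >= 2`), repeats or
#'   raters in columns (`k >= 2`), complete (no `NA`).
#' @param type ICC variant; only `"A1"` (two-way absolute agreement, single
#'   measure) is implemented, and the label is carried in the result.
#' @return A tibble with `icc`, `type`, `n_subjects`, `n_ratings`.
#' @examples
#' icc(cbind(c(10, 20, 30), c(11, 21, 31)))
#' @export
icc <- function(ratings, type = "A1") {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings)) stop("ratings must be numeric", call. = FALSE)
  if (anyNA(ratings)) stop("incomplete ratings matrix: remove or impute NAs",
                           call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) {
    stop("need >= 2 subjects and >= 2 measurements per subject", call. = FALSE)
  }
  grand <- mean(ratings)
  MSR <- k * stats::var(rowMeans(ratings))          # between subjects
  MSC <- n * stats::var(colMeans(ratings))          # between measurements
  SSE <- sum((ratings - grand)^2) - (n - 1) * MSR - (k - 1) * MSC
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  tibble::tibble(icc = (MSR - MSE) / denom, type = type,
                 n_subjects = n, n_ratings = k)
}

#' Bland-Altman analysis of paired measurements
#'
#' Differences are oriented `measured - calculated` (first minus second
#' argument). Limits of agreement are `mean_diff +/- 1.96 * sd_diff` with the
#' sample SD and the conventional normal-quantile 1.96 (not t-adjusted).
#'
#' @param measured,calculated Equal-length numeric vectors, `n >= 2`.
#' @return A list of class `bland_altman` with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, and `points` (tibble of per-pair `mean`, `diff`
#'   for plotting).
#' @examples
#' bland_altman(c(10, 12), c(11, 11))
#' @export
bland_altman <- function(measured, calculated) {
  stopifnot(is.numeric(measured), is.numeric(calculated))
  if (length(measured) != length(calculated)) {
    stop("series must have equal length", call. = FALSE)
  }
  if (length(measured) < 2L) stop("need n >= 2 pairs", call. = FALSE)
  if (anyNA(measured) || anyNA(calculated)) {
    stop("missing values; filter explicitly", call. = FALSE)
  }
  d <- measured - calculated
  m <- (measured + calculated) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(mean_diff = mean_diff, sd_diff = sd_diff,
                 loa_low = mean_diff - 1.96 * sd_diff,
                 loa_high = mean_diff + 1.96 * sd_diff,
                 points = tibble::tibble(mean = m, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> (measured - calculated) mean %.3f, SD %.3f, LoA [%.3f, %.3f], n = %d\n",
    x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Difference-versus-mean scatter with the mean difference and the 95%
#' limits of agreement as horizontal lines.
#'
#' @param ba A [bland_altman()] result.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, title = NULL) {
  stopifnot(inherits(ba, "bland_altman"))
  ggplot2::ggplot(ba$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of measured and calculated AL (mm)",
                  y = "Measured - calculated AL (mm)", title = title) +
    ggplot2::theme_minimal()
}

#' Summary of absolute differences between paired measurements
#'
#' [descriptive_summary()] applied to `|x - y|`; reporting only absolute
#' values avoids positive and negative deviations cancelling and gives the
#' clinically interpretable magnitude of disagreement in mm.
#'
#' @param x,y Equal-length numeric vectors, `n >= 2`.
#' @return A tibble as from [descriptive_summary()].
#' @examples
#' absolute_difference_summary(c(1, 2, 3), c(1.5, 2, 2.5))
#' @export
absolute_difference_summary <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("series must have equal length",
                                   call. = FALSE)
  descriptive_summary(abs(x - y))
}

#' Validate the arch-length model on a cohort stratum
#'
#' For one jaw and timepoint, computes the model arch length from the
#' *measured* depth and width (per side, and for the total arch with
#' `L_total = (L_left + L_right) / 2` and `W_total = W_left + W_right`),
#' pairs it with the measured arch length (total = left + right), and
#' reports the full set of agreement statistics per stratum.
#'
#' @param cohort Cohort tibble as produced by [generate_cohort()] or read
#'   from a cast table (needs `patient_id`, `jaw`, `side`, `timepoint`,
#'   `L_meas`, `W_meas`, `AL_meas`; per-side `AL_meas` is the half-arch
#'   length of that side).
#' @param timepoint `"T0"` or `"T1"`.
#' @param jaw `"upper"` or `"lower"`.
#' @return An `agreement_report`: list with `stratum` (jaw, timepoint),
#'   `pairs` (tibble of patient, side, `AL_meas`, `AL_calc`), and per side
#'   (`right`, `left`, `total`) a list holding `ccc`, `icc`, `bland_altman`,
#'   `abs_diff`, and `descriptives` for both series. Differences everywhere
#'   are oriented measured - calculated.
#' @examples
#' co <- generate_cohort(cohort_spec(n = 8), seed = 42)
#' validate_cohort(co, "T0", "upper")
#' @export
validate_cohort <- function(cohort, timepoint, jaw) {
  stopifnot(is.data.frame(cohort))
  timepoint <- match.arg(timepoint, c("T0", "T1"))
  jaw <- match.arg(jaw, c("upper", "lower"))
  needed <- c("patient_id", "jaw", "side", "timepoint",
              "L_meas", "W_meas", "AL_meas")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  str_rows <- cohort[cohort$jaw == jaw & cohort$timepoint == timepoint, ]
  if (nrow(str_rows) == 0L) {
    stop("empty stratum: no rows for jaw = ", jaw, ", timepoint = ",
         timepoint, call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    str_rows[, c("patient_id", "side", "L_meas", "W_meas", "AL_meas")],
    names_from = "side", values_from = c("L_meas", "W_meas", "AL_meas"))
  if (!all(c("L_meas_left", "L_meas_right") %in% names(wide))) {
    stop("stratum must contain both sides for every patient", call. = FALSE)
  }
  calc_half <- function(L, W) {
    vapply(seq_along(L), function(i) {
      half_arch_length(arch_geometry(L = L[i], W = W[i]))
    }, numeric(1))
  }
  pairs <- dplyr::bind_rows(
    tibble::tibble(patient_id = wide$patient_id, series = "right",
                   AL_meas = wide$AL_meas_right,
                   AL_calc = calc_half(wide$L_meas_right, wide$W_meas_right)),
    tibble::tibble(patient_id = wide$patient_id, series = "left",
                   AL_meas = wide$AL_meas_left,
                   AL_calc = calc_half(wide$L_meas_left, wide$W_meas_left)),
    tibble::tibble(patient_id = wide$patient_id, series = "total",
                   AL_meas = wide$AL_meas_left + wide$AL_meas_right,
                   AL_calc = vapply(seq_len(nrow(wide)), function(i) {
                     anterior_arch_length(
                       L = (wide$L_meas_left[i] + wide$L_meas_right[i]) / 2,
                       aaw = wide$W_meas_left[i] + wide$W_meas_right[i])
                   }, numeric(1)))
  )
  one <- function(sub) {
    list(ccc = lin_ccc(sub$AL_meas, sub$AL_calc),
         icc = icc(cbind(measured = sub$AL_meas, calculated = sub$AL_calc)),
         bland_altman = bland_altman(sub$AL_meas, sub$AL_calc),
         abs_diff = absolute_difference_summary(sub$AL_meas, sub$AL_calc),
         descriptives = list(
           measured = descriptive_summary(sub$AL_meas),
           calculated = descriptive_summary(sub$AL_calc)))
  }
  structure(list(
    stratum = list(jaw = jaw, timepoint = timepoint,
                   n_patients = nrow(wide)),
    pairs = pairs,
    right = one(pairs[pairs$series == "right", ]),
    left = one(pairs[pairs$series == "left", ]),
    total = one(pairs[pairs$series == "total", ])),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %s jaw at %s, n = %d patients\n",
              x$stratum$jaw, x$stratum$timepoint, x$stratum$n_patients))
  cat("  differences oriented measured - calculated\n")
  for (s in c("right", "left", "total")) {
    r <- x[[s]]
    cat(sprintf(
      "  %-6s CCC %.3f [%.3f, %.3f]  ICC(%s) %.3f  |diff| mean %.2f mm (max %.2f)\n",
      s, r$ccc$ccc, r$ccc$ci_low, r$ccc$ci_high, r$icc$type, r$icc$icc,
      r$abs_diff$mean, r$abs_diff$max))
  }
  invisible(x)
}

#' Flatten an agreement report to a tidy table
#'
#' One row per stratum series and statistic, mirroring a
#' stratum/statistic/value layout suitable for CSV export.
#'
#' @param report An `agreement_report`.
#' @return A tibble with columns `series`, `statistic`, `value`.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  rows <- lapply(c("right", "left", "total"), function(s) {
    r <- report[[s]]
    tibble::tibble(
      series = s,
      statistic = c("ccc", "ccc_ci_low", "ccc_ci_high", "icc",
                    "mean_diff", "sd_diff", "loa_low", "loa_high",
                    "abs_diff_mean", "abs_diff_sd", "abs_diff_min",
                    "abs_diff_max", "abs_diff_ci_low", "abs_diff_ci_high",
                    "mean_measured", "sd_measured",
                    "mean_calculated", "sd_calculated"),
      value = c(r$ccc$ccc, r$ccc$ci_low, r$ccc$ci_high, r$icc$icc,
                r$bland_altman$mean_diff, r$bland_altman$sd_diff,
                r$bland_altman$loa_low, r$bland_altman$loa_high,
                r$abs_diff$mean, r$abs_diff$sd, r$abs_diff$min,
                r$abs_diff$max, r$abs_diff$ci_low, r$abs_diff$ci_high,
                r$descriptives$measured$mean, r$descriptives$measured$sd,
                r$descriptives$calculated$mean, r$descriptives$calculated$sd))
  })
  dplyr::bind_rows(rows)
}
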