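#' Regress predicted thresholds on measured optimal thresholds
#'
#' Ordinary least squares of predicted on measured (measured on the
#' x-axis): a method that tracks the optimal threshold has slope near 1,
#' intercept near 0 and high R^2, while a fixed single-threshold method
#' degenerates to slope 0.
#'
#' @param predicted,measured numeric vectors of thresholds (same units,
#'   e.g. % of ACmax); pairs with `NA` in either are dropped.
#' @return object of class `regression_summary`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
regress_predicted_vs_measured <- function(predicted, measured) {
  ok <- is.finite(predicted) & is.finite(measured)
  predicted <- predicted[ok]; measured <- measured[ok]
  n <- length(predicted)
  if (n < 2L) stop("regression needs at least 2 finite pairs", call. = FALSE)
  if (stats::var(measured) == 0)
    stop("zero variance in the measured thresholds", call. = FALSE)
  fit <- stats::lm(predicted ~ measured)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n = n),
    class = "regression_summary"
  )
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("predicted = %.3g * measured + %.3g (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Paired comparison of PET and reference ITV volumes
#'
#' Two-sided paired t-test of per-lesion PET-minus-reference volume
#' differences.  Lesions whose PET segmentation was flagged not
#' segmentable (`NA` volume) are excluded pairwise and the remaining count
#' reported.  The percent difference is the mean paired difference as a
#' percentage of the mean reference volume over the same paired subset.
#'
#' @param pet_volumes_cm3 per-lesion PET ITV volumes; `NA` marks a
#'   not-segmentable lesion.
#' @param ct_volumes_cm3 per-lesion reference (CT) ITV volumes, aligned.
#' @return object of class `paired_comparison`: `n_pairs`,
#'   `mean_pet_volume`, `sem_pet_volume`, `mean_ct_volume`,
#'   `mean_difference`, `sem_difference`, `percent_difference`, `p_value`.
#' @export
paired_volume_comparison <- function(pet_volumes_cm3, ct_volumes_cm3) {
  if (length(pet_volumes_cm3) != length(ct_volumes_cm3))
    stop("volume lists must be aligned per lesion", call. = FALSE)
  ok <- is.finite(pet_volumes_cm3) & is.finite(ct_volumes_cm3)
  pet <- pet_volumes_cm3[ok]; ct <- ct_volumes_cm3[ok]
  n <- length(pet)
  if (n < 2L) stop("need at least 2 valid pairs", call. = FALSE)
  d <- pet - ct
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  p <- if (stats::sd(d) == 0) 1 else stats::t.test(pet, ct, paired = TRUE)$p.value
  structure(
    list(n_pairs = n,
         mean_pet_volume = mean(pet), sem_pet_volume = sem(pet),
         mean_ct_volume = mean(ct),
         mean_difference = mean(d), sem_difference = sem(d),
         percent_difference = 100 * mean(d) / mean(ct),
         p_value = p),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired ITV comparison (n = %d):\n", x$n_pairs))
  cat(sprintf("  PET volume %.4g +/- %.3g cm^3, reference %.4g cm^3\n",
              x$mean_pet_volume, x$sem_pet_volume, x$mean_ct_volume))
  cat(sprintf("  difference %+.4g +/- %.3g cm^3 (%+.3g%%), p = %.3g\n",
              x$mean_difference, x$sem_difference, x$percent_difference,
              x$p_value))
  invisible(x)
}
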