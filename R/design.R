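#' Repeated measures needed to reach a target construct-level stability
#'
#' Solves the decision-study question: how many independent repeated measures
#' N does a design need before the construct-level reliability
#' \eqn{ICC2 = \sigma^2_B / (\sigma^2_B + \sigma^2_E / N)} strictly exceeds a
#' target? Equivalently, the smallest integer with
#' \eqn{N > \frac{target}{1 - target} \cdot \frac{\sigma^2_E}{\sigma^2_B}}
#' (for the default target .9 the factor is 9). Supply either a single-measure
#' `icc` (converted via \eqn{\sigma^2_E / \sigma^2_B = (1 - ICC)/ICC}) or the
#' component pair - exactly one of the two.
#'
#' @param icc Single-measure ICC in (0, 1].
#' @param sigma_b2,sigma_e2 Variance components (alternative to `icc`).
#' @param target_icc2 Target construct-level stability in (0, 1); default .9.
#' @return Smallest integer N strictly meeting the target (1 when the error
#'   variance is zero); `Inf` when the between-subjects variance is zero (the
#'   target is unattainable).
#' @details The strict inequality is enforced with a 1e-8 tolerance so that an
#'   exact boundary (e.g. ICC = .9, target = .9, where the bound is exactly 1)
#'   rounds up to the next integer rather than being lost to floating-point
#'   noise.
#' @examples
#' required_timepoints(icc = 0.54)             # 8
#' required_timepoints(icc = 0.9)              # 2: boundary forces one more
#' required_timepoints(sigma_b2 = 1, sigma_e2 = 0)  # 1
#' @export
required_timepoints <- function(icc = NULL, sigma_b2 = NULL, sigma_e2 = NULL,
                                target_icc2 = 0.9) {
  stopifnot(is.numeric(target_icc2), target_icc2 > 0, target_icc2 < 1)
  if (!is.null(icc) && (!is.null(sigma_b2) || !is.null(sigma_e2))) {
    stop("supply either `icc` or the (sigma_b2, sigma_e2) pair, not both",
         call. = FALSE)
  }
  if (!is.null(icc)) {
    stopifnot(is.numeric(icc), icc >= 0, icc <= 1)
    if (icc == 0) return(Inf)
    ratio <- (1 - icc) / icc
  } else {
    stopifnot(is.numeric(sigma_b2), is.numeric(sigma_e2),
              sigma_b2 >= 0, sigma_e2 >= 0)
    if (sigma_b2 == 0) return(Inf)
    ratio <- sigma_e2 / sigma_b2
  }
  bound <- target_icc2 / (1 - target_icc2) * ratio
  max(1L, as.integer(floor(bound + 1e-8)) + 1L)
}

#' Attenuation of a correlation under imperfect reliability
#'
#' Spearman's attenuation formula: the observed correlation between two
#' imperfectly reliable variables is
#' \eqn{r_{obs} = r_{true} \sqrt{rel_x} \sqrt{rel_y}}. Symmetric and
#' multiplicative in the two reliabilities; the observed value never exceeds
#' the true one in magnitude.
#'
#' @param r_true True correlation in (-1, 1).
#' @param rel_x,rel_y Reliabilities (e.g. longitudinal stability ICCs) in
#'   (0, 1].
#' @return The attenuated correlation.
#' @examples
#' attenuated_correlation(0.3, 0.9, 0.9)   # 0.27
#' attenuated_correlation(0.3, 0.9, 0.54)  # ~0.21
#' @export
attenuated_correlation <- function(r_true, rel_x, rel_y) {
  stopifnot(is.numeric(r_true), abs(r_true) < 1,
            is.numeric(rel_x), rel_x > 0, rel_x <= 1,
            is.numeric(rel_y), rel_y > 0, rel_y <= 1)
  r_true * sqrt(rel_x) * sqrt(rel_y)
}

#' Sample size to detect a correlation
#'
#' Two-sided Fisher-z sample size: solves
#' \eqn{\sqrt{n - 3}\, \mathrm{atanh}(|r|) = z_{1-\alpha/2} + z_{power}} and
#' reports the integer part of the solution (set `conservative = TRUE` to
#' round up instead).
#'
#' @param r Correlation to detect, 0 < |r| < 1.
#' @param power Desired power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param conservative Round the solved n up rather than truncating.
#' @return Required sample size (>= 4); `Inf` for r = 0.
#' @examples
#' sample_size_for_correlation(0.27)  # 105
#' sample_size_for_correlation(0.21)  # 175
#' @export
sample_size_for_correlation <- function(r, power = 0.8, alpha = 0.05,
                                        conservative = FALSE) {
  stopifnot(is.numeric(r), abs(r) < 1,
            is.numeric(power), power > 0, power < 1,
            is.numeric(alpha), alpha > 0, alpha < 1)
  if (r == 0) return(Inf)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- (z / atanh(abs(r)))^2 + 3
  n <- if (conservative) ceiling(n - 1e-9) else floor(n + 1e-9)
  max(4L, as.integer(n))
}

#' Attenuation and power report across regions
#'
#' For each row of a query table, computes the attenuated correlation, the
#' sample size needed to detect it, and the percent extra participants
#' relative to the least demanding row - the practical cost of stability
#' heterogeneity across regions.
#'
#' @param queries Data frame with columns `label`, `rel_region`, and
#'   optionally `r_true` (default .3), `rel_measure` (default .9), `power`
#'   (default .8), `alpha` (default .05).
#' @param digits Attenuated correlations are rounded to this many decimals
#'   before the sample-size step, matching how such effect sizes are reported
#'   and then plugged into power calculations; set `NA` to use full precision.
#' @return The input with added columns `r_observed`, `n_required`,
#'   `pct_extra_participants`.
#' @examples
#' attenuation_power_report(data.frame(label = c("parahippocampal", "temporalpole"),
#'                                     rel_region = c(0.9, 0.54)))
#' @export
attenuation_power_report <- function(queries, digits = 2) {
  stopifnot(is.data.frame(queries), nrow(queries) >= 1,
            all(c("label", "rel_region") %in% names(queries)))
  defaults <- list(r_true = 0.3, rel_measure = 0.9, power = 0.8, alpha = 0.05)
  for (nm in names(defaults)) {
    if (is.null(queries[[nm]])) queries[[nm]] <- defaults[[nm]]
  }
  queries$r_observed <- mapply(attenuated_correlation, queries$r_true,
                               queries$rel_measure, queries$rel_region)
  if (!is.na(digits)) queries$r_observed <- round(queries$r_observed, digits)
  queries$n_required <- mapply(sample_size_for_correlation,
                               queries$r_observed, queries$power,
                               queries$alpha)
  finite <- is.finite(queries$n_required)
  best <- if (any(finite)) min(queries$n_required[finite]) else NA_real_
  queries$pct_extra_participants <- 100 * (queries$n_required / best - 1)
  queries
}
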