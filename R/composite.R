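#' Upper-tertile cutpoint for SOC totals
#'
#' Sense of coherence has no established clinical threshold, so "normal" SOC
#' is defined as the highest tertile of the score distribution: strictly above
#' the empirical 2/3-quantile. The quantile is nearest-rank (the
#' \eqn{\lceil 2n/3 \rceil}-th order statistic); scores tied with the cutpoint
#' fall on the "low" side because normality requires a strict ">".
#'
#' @param scores numeric vector of SOC totals; \code{NA}s dropped.
#' @return the cutpoint (a score value).
#' @examples
#' soc_tertile_cutpoint(c(13, 50, 91))  # 50: only 91 counts as normal
#' @export
soc_tertile_cutpoint <- function(scores) {
  s <- sort(scores[!is.na(scores)])
  if (length(s) < 3) stop("need at least 3 non-missing SOC scores", call. = FALSE)
  s[ceiling(2 * length(s) / 3)]
}

#' Classify respondents on the four-level composite indicator
#'
#' Crosses the SOC dichotomy (normal = strictly above the tertile cutpoint)
#' with the GHQ distress dichotomy into the 2x2 composite: resilient
#' (normal SOC, normal GHQ), vulnerable (low SOC, high GHQ), and the two
#' non-classifiable cells with conflicting results. Respondents missing either
#' input get \code{NA} and are excluded from composite analyses
#' (available-case).
#'
#' @param soc_cat character \code{"normal"}/\code{"low"} or SOC totals (then
#'   dichotomized at \code{soc_cutpoint}).
#' @param distress_cat character \code{"high"}/\code{"normal"} (from
#'   [classify_distress()]).
#' @param soc_cutpoint used only when \code{soc_cat} is numeric; default 65,
#'   the study's fixed upper-tertile cut. Use
#'   \code{soc_tertile_cutpoint(scores)} for an empirical cut.
#' @return factor with levels nonclass_normalSoC_highGHQ, resilient,
#'   nonclass_lowSoC_normalGHQ, vulnerable.
#' @export
classify_composite <- function(soc_cat, distress_cat, soc_cutpoint = 65) {
  if (is.numeric(soc_cat)) {
    soc_cat <- ifelse(is.na(soc_cat), NA_character_,
                      ifelse(soc_cat > soc_cutpoint, "normal", "low"))
  }
  stopifnot(all(soc_cat %in% c("normal", "low") | is.na(soc_cat)),
            all(distress_cat %in% c("high", "normal") | is.na(distress_cat)))
  lab <- ifelse(is.na(soc_cat) | is.na(distress_cat), NA_character_,
    ifelse(soc_cat == "normal",
      ifelse(distress_cat == "normal", "resilient", "nonclass_normalSoC_highGHQ"),
      ifelse(distress_cat == "high", "vulnerable", "nonclass_lowSoC_normalGHQ")))
  factor(lab, levels = COMPOSITE_LEVELS)
}

#' Attach SOC category and composite label to a scored cohort
#'
#' @param cohort a \code{scored_cohort} from [score_cohort()].
#' @param tertile \code{"fixed"} (use \code{soc_cutpoint}) or
#'   \code{"empirical"} (recompute the upper-tertile cut from this cohort's
#'   non-missing SOC totals).
#' @param soc_cutpoint fixed SOC cut (normal = strictly above); default 65.
#' @return the cohort with added \code{soc_cat} and \code{composite} columns;
#'   the cutpoint actually used is stored in \code{attr(, "soc_cutpoint")}.
#' @export
classify_cohort <- function(cohort, tertile = c("fixed", "empirical"),
                            soc_cutpoint = 65) {
  tertile <- match.arg(tertile)
  cut <- if (tertile == "empirical") soc_tertile_cutpoint(cohort$soc_total) else soc_cutpoint
  cohort$soc_cat <- ifelse(is.na(cohort$soc_total), NA_character_,
                           ifelse(cohort$soc_total > cut, "normal", "low"))
  cohort$composite <- classify_composite(cohort$soc_cat, cohort$distress)
  attr(cohort, "soc_cutpoint") <- cut
  cohort
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval without continuity correction, as returned by inverting
#' the score test (\code{prop.test(correct = FALSE)}).
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param level confidence level.
#' @return named numeric \code{c(estimate, lower, upper)}.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n, level > 0, level < 1)
  # the score interval itself is exact algebra; prop.test's chi-squared
  # approximation warning concerns its test, not the interval
  ci <- suppressWarnings(prop.test(x, n, conf.level = level, correct = FALSE))$conf.int
  c(estimate = x / n, lower = ci[1], upper = ci[2])
}

#' Composite category prevalences with Wilson intervals
#'
#' Proportions are over respondents with a non-missing composite label
#' (available-case) and sum to 1.
#'
#' @param cohort a classified cohort (see [classify_cohort()]), or a factor of
#'   composite labels.
#' @param ci_level confidence level for the Wilson intervals.
#' @return tibble with \code{category}, \code{n}, \code{proportion},
#'   \code{lower}, \code{upper}; one row per composite level.
#' @export
category_proportions <- function(cohort, ci_level = 0.95) {
  labels <- if (is.data.frame(cohort)) cohort$composite else cohort
  labels <- factor(labels, levels = COMPOSITE_LEVELS)
  labels <- labels[!is.na(labels)]
  n <- length(labels)
  if (n == 0) stop("no respondents with a composite category", call. = FALSE)
  counts <- table(labels)
  ci <- t(vapply(as.integer(counts), wilson_ci, numeric(3), n = n, level = ci_level))
  tibble::tibble(
    category = names(counts),
    n = as.integer(counts),
    proportion = as.integer(counts) / length(labels),
    lower = ci[, "lower"],
    upper = ci[, "upper"]
  )
}
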