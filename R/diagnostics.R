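#' Cross-tabulate a multi-level test against a binary reference
#'
#' @param test factor/character of test levels (e.g. composite categories).
#' @param reference logical (TRUE = reference-positive) or a vector coercible
#'   to logical.
#' @param levels level set and declaration order; defaults to the levels
#'   present.
#' @return a \code{diagnostic_table}: list with \code{levels},
#'   \code{counts_pos}, \code{counts_neg} (counts per level in each reference
#'   arm). Pairs with a missing test level or reference are dropped
#'   (available-case).
#' @export
diagnostic_table <- function(test, reference, levels = NULL) {
  reference <- as.logical(reference)
  keep <- !is.na(test) & !is.na(reference)
  test <- factor(test[keep], levels = levels %||% levels(factor(test[keep])))
  reference <- reference[keep]
  out <- structure(list(
    levels = levels(test),
    counts_pos = as.integer(table(test[reference])),
    counts_neg = as.integer(table(test[!reference]))
  ), class = "diagnostic_table")
  validate_diagnostic_table(out)
  out
}

#' Build a diagnostic table directly from counts
#'
#' @param levels character vector of ordered-as-declared level names.
#' @param counts_pos,counts_neg non-negative integer counts per level among
#'   reference-positive / reference-negative subjects.
#' @export
diagnostic_table_counts <- function(levels, counts_pos, counts_neg) {
  out <- structure(list(
    levels = as.character(levels),
    counts_pos = as.integer(counts_pos),
    counts_neg = as.integer(counts_neg)
  ), class = "diagnostic_table")
  validate_diagnostic_table(out)
  out
}

validate_diagnostic_table <- function(x) {
  stopifnot(length(x$counts_pos) == length(x$levels),
            length(x$counts_neg) == length(x$levels))
  if (any(x$counts_pos < 0) || any(x$counts_neg < 0)) {
    stop("diagnostic table counts must be non-negative", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.diagnostic_table <- function(x, ...) {
  cat("Diagnostic table (", length(x$levels), " test levels)\n", sep = "")
  print(data.frame(level = x$levels, pos = x$counts_pos, neg = x$counts_neg),
        row.names = FALSE)
  invisible(x)
}

#' Multi-level likelihood ratios
#'
#' For each test level c, \eqn{LR_c = P(c \mid ref+) / P(c \mid ref-)}. Using
#' all levels avoids dichotomizing the test: LR+ is the LR of the most
#' at-risk level (vulnerable) and LR- that of the most protective (resilient).
#' A level observed only among reference-positives gets \code{Inf}; a level
#' observed in neither arm gets \code{NaN} (undefined). With
#' \code{smooth = TRUE}, Haldane-style +0.5 is added to every cell first
#' (off by default: a raw zero count is itself informative).
#'
#' @param table a \code{diagnostic_table}.
#' @param smooth add 0.5 to every cell before forming ratios.
#' @return named numeric vector of LRs, one per level.
#' @export
multilevel_lr <- function(table, smooth = FALSE) {
  validate_diagnostic_table(table)
  pos <- table$counts_pos
  neg <- table$counts_neg
  if (sum(pos) == 0 || sum(neg) == 0) {
    stop("both reference arms must be non-empty to compute likelihood ratios",
         call. = FALSE)
  }
  if (smooth) {
    pos <- pos + 0.5
    neg <- neg + 0.5
  }
  p_pos <- pos / sum(pos)
  p_neg <- neg / sum(neg)
  lr <- p_pos / p_neg       # 0/0 -> NaN, x/0 -> Inf, as documented
  names(lr) <- table$levels
  lr
}

#' Bayes post-test probability
#'
#' Converts a pretest prevalence to odds, multiplies by the likelihood ratio
#' of the observed test level, and converts back:
#' \eqn{post = odds \cdot LR / (1 + odds \cdot LR)} with
#' \eqn{odds = p/(1-p)}.
#'
#' @param prevalence pretest probability in (0, 1).
#' @param lr likelihood ratio(s), \eqn{\ge 0}; vectorized.
#' @return post-test probability, same length as \code{lr}.
#' @examples
#' bayes_posttest(0.207, 2.61)   # ~0.405
#' bayes_posttest(0.207, 0.054)  # ~0.014
#' @export
bayes_posttest <- function(prevalence, lr) {
  stopifnot(prevalence > 0, prevalence < 1, all(lr >= 0 | is.nan(lr)))
  odds <- prevalence / (1 - prevalence) * lr
  ifelse(is.infinite(odds), 1, odds / (1 + odds))
}

#' Invert a post-test probability to the pretest prevalence
#'
#' Given a post-test probability and the LR that produced it, recovers the
#' pretest prevalence: \eqn{p = o/(1+o)} with
#' \eqn{o = (post/(1-post))/LR}.
#'
#' @param posttest post-test probability in (0, 1).
#' @param lr positive likelihood ratio.
#' @export
bayes_pretest <- function(posttest, lr) {
  stopifnot(posttest > 0, posttest < 1, lr > 0)
  o <- (posttest / (1 - posttest)) / lr
  o / (1 + o)
}

#' Predictive values from a 2x2 table
#'
#' \eqn{PPV = TP/(TP+FP)}, \eqn{NPV = TN/(TN+FN)}. On the same table these
#' coincide exactly with the Bayes post-test probabilities computed from the
#' table's prevalence and LRs. A zero margin yields \code{NaN} with a warning
#' rather than an error.
#'
#' @param tp,fp,fn,tn cell counts (test-positive/negative x reference
#'   positive/negative).
#' @return named numeric \code{c(ppv, npv)}.
#' @export
predictive_values <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  if (tp + fp == 0 || tn + fn == 0) {
    warning("zero test margin: predictive value undefined (NaN)", call. = FALSE)
  }
  c(ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Nonparametric AUC for an ordinal multi-level test
#'
#' The area under the empirical ROC curve over the K ordered test levels,
#' computed exactly from the grouped counts as the tie-corrected Mann-Whitney
#' probability \eqn{P(rank_{pos} > rank_{neg}) + \frac12 P(rank_{pos} =
#' rank_{neg})} (equivalently, the trapezoidal area).
#'
#' @param table a \code{diagnostic_table}.
#' @param ordering \code{"lr"} (default): rank levels by their estimated LR,
#'   ascending, ties broken by declaration order — the canonical risk ordering
#'   for a multi-level test; \code{"declared"}: use the declaration order as
#'   increasing risk.
#' @return the AUC (scalar in [0, 1]).
#' @export
roc_auc_ordinal <- function(table, ordering = c("lr", "declared")) {
  validate_diagnostic_table(table)
  ordering <- match.arg(ordering)
  n_pos <- sum(table$counts_pos)
  n_neg <- sum(table$counts_neg)
  if (n_pos == 0 || n_neg == 0) stop("both arms must be non-empty", call. = FALSE)
  if (length(table$levels) < 2) stop("need at least 2 test levels", call. = FALSE)
  ord <- if (ordering == "lr") {
    lr <- multilevel_lr(table)
    lr[is.nan(lr)] <- -Inf   # empty levels contribute nothing; rank first
    order(lr, seq_along(lr))
  } else {
    seq_along(table$levels)
  }
  pos <- table$counts_pos[ord] / n_pos
  neg <- table$counts_neg[ord] / n_neg
  cum_neg <- cumsum(neg) - neg   # P(neg strictly below this level)
  sum(pos * (cum_neg + 0.5 * neg))
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Standard error from the grouped-count formula of Hanley & McNeil with
#' \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}, and a Wald interval clipped
#' to [0, 1]. Chosen because it needs only the arm sizes, not per-subject
#' predictors.
#'
#' @param auc the estimated AUC.
#' @param n_pos,n_neg reference-positive / negative arm sizes.
#' @param level confidence level.
#' @return named numeric \code{c(auc, se, lower, upper)}.
#' @export
auc_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  stopifnot(n_pos > 0, n_neg > 0, auc >= 0, auc <= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (as.double(n_pos) * n_neg))
  if (auc %in% c(0, 1)) {
    warning("degenerate AUC: interval collapses to a point", call. = FALSE)
  }
  z <- qnorm(1 - (1 - level) / 2)
  c(auc = auc, se = se,
    lower = max(0, auc - z * se), upper = min(1, auc + z * se))
}

#' Two-sample test of proportions (pooled z)
#'
#' Large-sample z-test with pooled variance,
#' \eqn{z = (p_1 - p_2)/\sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)}}, two-sided p.
#'
#' @param p1,n1 proportion and size of sample 1.
#' @param p2,n2 proportion and size of sample 2.
#' @return named numeric \code{c(z, p_value)}.
#' @export
two_sample_proportion_test <- function(p1, n1, p2, n2) {
  stopifnot(n1 > 0, n2 > 0, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  v <- pbar * (1 - pbar) * (1 / n1 + 1 / n2)
  if (v == 0) stop("pooled variance is zero; test undefined", call. = FALSE)
  z <- (p1 - p2) / sqrt(v)
  c(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Chi-squared / Fisher test for a contingency table
#'
#' Pearson chi-squared without continuity correction for r x c tables; for a
#' 2x2 table with any expected cell below 5 the method switches to Fisher's
#' exact test automatically (overridable).
#'
#' @param counts matrix of non-negative counts.
#' @param method \code{"auto"}, \code{"chi2"} or \code{"fisher"}.
#' @return named numeric \code{c(p_value)} with attribute \code{"method"}.
#' @export
contingency_test <- function(counts, method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate margins: a row or column is all zero", call. = FALSE)
  }
  if (method == "auto") {
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    method <- if (all(dim(counts) == c(2, 2)) && any(expected < 5)) "fisher" else "chi2"
  }
  p <- if (method == "fisher") {
    fisher.test(counts)$p.value
  } else {
    suppressWarnings(chisq.test(counts, correct = FALSE))$p.value
  }
  structure(c(p_value = p), method = method)
}

#' Evaluate the composite indicator against a reference standard
#'
#' Full diagnostic evaluation of a multi-level test: per-level likelihood
#' ratios, pretest prevalence, Bayes post-test probabilities for the
#' vulnerable (LR+) and resilient (LR-) levels, PPV/NPV of the
#' vulnerable-vs-rest and resilient-vs-rest dichotomies, and the
#' nonparametric ordinal AUC with its Hanley-McNeil interval.
#'
#' @param table a \code{diagnostic_table} whose levels include
#'   \code{positive_level} and \code{negative_level}.
#' @param positive_level level treated as the test-positive call (LR+);
#'   default \code{"vulnerable"}.
#' @param negative_level level treated as the test-negative call (LR-);
#'   default \code{"resilient"}.
#' @param ci_level confidence level for the AUC interval.
#' @return an \code{eval_report} list: \code{lr} (per level),
#'   \code{prevalence}, \code{lr_pos}, \code{lr_neg}, \code{posttest_pos},
#'   \code{posttest_neg}, \code{ppv}, \code{npv}, \code{auc} (with CI),
#'   \code{n_pos}, \code{n_neg}.
#' @export
evaluate_indicator <- function(table, positive_level = "vulnerable",
                               negative_level = "resilient", ci_level = 0.95) {
  validate_diagnostic_table(table)
  stopifnot(positive_level %in% table$levels, negative_level %in% table$levels)
  lr <- multilevel_lr(table)
  n_pos <- sum(table$counts_pos)
  n_neg <- sum(table$counts_neg)
  prev <- n_pos / (n_pos + n_neg)
  i_pos <- match(positive_level, table$levels)
  i_neg <- match(negative_level, table$levels)
  # vulnerable-vs-rest 2x2 for PPV; resilient-vs-rest for NPV
  ppv <- predictive_values(
    tp = table$counts_pos[i_pos], fp = table$counts_neg[i_pos],
    fn = n_pos - table$counts_pos[i_pos], tn = n_neg - table$counts_neg[i_pos]
  )[["ppv"]]
  npv <- predictive_values(
    tp = n_pos - table$counts_pos[i_neg], fp = n_neg - table$counts_neg[i_neg],
    fn = table$counts_pos[i_neg], tn = table$counts_neg[i_neg]
  )[["npv"]]
  auc <- roc_auc_ordinal(table)
  structure(list(
    lr = lr,
    prevalence = prev,
    lr_pos = lr[[positive_level]],
    lr_neg = lr[[negative_level]],
    posttest_pos = bayes_posttest(prev, lr[[positive_level]]),
    posttest_neg = bayes_posttest(prev, lr[[negative_level]]),
    ppv = ppv,
    npv = npv,
    auc = auc_ci(auc, n_pos, n_neg, level = ci_level),
    ci_level = ci_level,
    n_pos = n_pos,
    n_neg = n_neg
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Diagnostic evaluation of a multi-level indicator\n")
  cat(sprintf("  reference-positive: %d, reference-negative: %d (prevalence %.3f)\n",
              x$n_pos, x$n_neg, x$prevalence))
  cat("  likelihood ratios:\n")
  for (l in names(x$lr)) cat(sprintf("    %-28s %6.3f\n", l, x$lr[[l]]))
  cat(sprintf("  LR+ %.3f -> post-test %.3f | LR- %.3f -> post-test %.3f\n",
              x$lr_pos, x$posttest_pos, x$lr_neg, x$posttest_neg))
  cat(sprintf("  PPV %.1f%%  NPV %.1f%%\n", 100 * x$ppv, 100 * x$npv))
  cat(sprintf("  AUC %.3f (%.0f%% CI %.3f-%.3f)\n", x$auc[["auc"]],
              100 * x$ci_level, x$auc[["lower"]], x$auc[["upper"]]))
  invisible(x)
}

#' Analytic AUC from category marginals, LRs and prevalence
#'
#' Reconstructs the arm-conditional category distributions from pooled
#' marginals via Bayes — \eqn{P(c \mid D^-) = m_c / (p\,LR_c + 1 - p)} and
#' \eqn{P(c \mid D^+) = LR_c\, m_c / (p\,LR_c + 1 - p)} — normalizes each
#' arm, orders levels by ascending LR, and returns the tie-corrected
#' Mann-Whitney AUC. Useful when only published summaries, not subject-level
#' data, are available.
#'
#' @param marginals pooled category probabilities (sums to ~1).
#' @param lr per-category likelihood ratios, same order.
#' @param prevalence pretest probability of the reference condition.
#' @return the AUC.
#' @export
auc_from_marginals <- function(marginals, lr, prevalence) {
  stopifnot(length(marginals) == length(lr), all(marginals >= 0), all(lr >= 0),
            prevalence > 0, prevalence < 1)
  denom <- prevalence * lr + (1 - prevalence)
  p_neg <- marginals / denom
  p_pos <- lr * marginals / denom
  p_neg <- p_neg / sum(p_neg)
  p_pos <- p_pos / sum(p_pos)
  ord <- order(lr, seq_along(lr))
  p_pos <- p_pos[ord]
  p_neg <- p_neg[ord]
  cum_neg <- cumsum(p_neg) - p_neg
  sum(p_pos * (cum_neg + 0.5 * p_neg))
}

#' Compare a cohort's category prevalences with a reference population
#'
#' Runs the pooled two-sample proportion test per composite category against
#' published population percentages (e.g. the general-population 18-25 age
#' band shipped in \code{inst/extdata}).
#'
#' @param cohort_props tibble from [category_proportions()].
#' @param population data frame with columns \code{category} and
#'   \code{percent}; see [general_population_reference()].
#' @param population_n assumed population sample size for the test.
#' @return tibble with per-category proportions, z and p-values.
#' @export
compare_populations <- function(cohort_props, population, population_n) {
  stopifnot(all(c("category", "percent") %in% names(population)))
  m <- match(cohort_props$category, population$category)
  if (anyNA(m)) stop("population table lacks some categories", call. = FALSE)
  p2 <- population$percent[m] / 100
  n1 <- sum(cohort_props$n)
  res <- t(mapply(function(p1, p2) {
    if (p1 == p2) c(z = 0, p_value = 1) else two_sample_proportion_test(p1, n1, p2, population_n)
  }, cohort_props$proportion, p2))
  tibble::tibble(
    category = cohort_props$category,
    cohort_proportion = cohort_props$proportion,
    population_proportion = p2,
    z = res[, "z"],
    p_value = res[, "p_value"]
  )
}

#' Packaged general-population composite-category distribution
#'
#' Composite-indicator category percentages for 18-25-year-old adults from a
#' nationally representative mental-health survey, shipped as a CSV fixture
#' for [compare_populations()].
#'
#' @return data frame with \code{category}, \code{percent}.
#' @export
general_population_reference <- function() {
  read.csv(system.file("extdata", "general_population_18_25.csv",
                       package = "resilscreen"), stringsAsFactors = FALSE)
}
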