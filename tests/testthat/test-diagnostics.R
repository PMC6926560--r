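test_that("multi-level LR matches count arithmetic and flags degenerate levels", {
  # identical arm distributions -> all LRs 1
  t1 <- diagnostic_table_counts(c("a", "b"), c(5, 5), c(20, 20))
  expect_equal(unname(multilevel_lr(t1)), c(1, 1))
  # direct arithmetic: pos (8,2), neg (2,8)
  t2 <- diagnostic_table_counts(c("a", "b"), c(8, 2), c(2, 8))
  expect_equal(unname(multilevel_lr(t2)), c(4, 0.25))
  # zero negative count with positives -> Inf; zero/zero -> NaN
  t3 <- diagnostic_table_counts(c("a", "b", "c"), c(3, 2, 0), c(0, 5, 0))
  lr3 <- multilevel_lr(t3)
  expect_true(is.infinite(lr3[["a"]]))
  expect_true(is.nan(lr3[["c"]]))
  # Haldane smoothing removes the flags
  expect_true(all(is.finite(multilevel_lr(t3, smooth = TRUE))))
  expect_error(multilevel_lr(diagnostic_table_counts("a", 0, 5)), "non-empty")
})

test_that("Bayes post-test probability follows the odds arithmetic", {
  expect_equal(bayes_posttest(0.207, 2.61), 0.405, tolerance = 1e-3)
  expect_lt(abs(bayes_posttest(0.207, 0.054) - 0.014), 5e-4)
  # LR = 1 is uninformative at any prevalence
  for (p in c(0.01, 0.2, 0.5, 0.9)) expect_equal(bayes_posttest(p, 1), p)
  # inversion round-trip
  set.seed(31)
  for (i in 1:20) {
    p <- runif(1, 0.05, 0.95)
    lr <- runif(1, 0.1, 5)
    expect_equal(bayes_pretest(bayes_posttest(p, lr), lr), p, tolerance = 1e-12)
  }
  expect_error(bayes_posttest(0, 2))
  expect_error(bayes_posttest(1, 2))
})

test_that("predictive values come from the 2x2 margins", {
  pv <- predictive_values(tp = 4, fp = 6, fn = 1, tn = 89)
  expect_equal(unname(pv), c(0.40, 89 / 90))
  expect_equal(unname(predictive_values(10, 0, 0, 10)), c(1, 1))
  expect_warning(pv0 <- predictive_values(0, 0, 1, 9), "zero test margin")
  expect_true(is.nan(pv0[["ppv"]]))
})

test_that("PPV/NPV equal Bayes post-test values on the same table exactly", {
  set.seed(32)
  for (i in 1:100) {
    tab <- random_diag_table()
    lr <- multilevel_lr(tab)
    prev <- sum(tab$counts_pos) / (sum(tab$counts_pos) + sum(tab$counts_neg))
    for (j in seq_along(tab$levels)) {
      a <- tab$counts_pos[j]
      b <- tab$counts_neg[j]
      if (a + b == 0) next
      direct <- a / (a + b)  # P(ref+ | level) straight from counts
      expect_equal(bayes_posttest(prev, lr[[j]]), direct, tolerance = 1e-12)
    }
  }
})

test_that("ordinal AUC equals the brute-force pairwise probability", {
  flat <- diagnostic_table_counts(c("a", "b", "c"), c(4, 4, 4), c(10, 10, 10))
  expect_equal(roc_auc_ordinal(flat), 0.5)
  sep <- diagnostic_table_counts(c("lo", "hi"), c(0, 7), c(9, 0))
  expect_equal(roc_auc_ordinal(sep), 1)
  set.seed(33)
  for (i in 1:100) {
    tab <- random_diag_table()
    lr <- multilevel_lr(tab)
    lr[is.nan(lr)] <- -Inf
    ord <- order(lr, seq_along(lr))
    expect_equal(roc_auc_ordinal(tab),
                 brute_force_auc(tab$counts_pos[ord], tab$counts_neg[ord]))
  }
  expect_error(roc_auc_ordinal(diagnostic_table_counts(c("a", "b"), c(0, 0), c(1, 1))))
})

test_that("ordinal AUC agrees with pROC on per-subject expanded data", {
  skip_if_not_installed("pROC")
  set.seed(34)
  for (i in 1:20) {
    tab <- random_diag_table(n_levels = 4)
    lr <- multilevel_lr(tab)
    lr[is.nan(lr)] <- -Inf
    ord <- order(lr, seq_along(lr))
    ranks <- c(rep(seq_along(ord), tab$counts_pos[ord]),
               rep(seq_along(ord), tab$counts_neg[ord]))
    labels <- c(rep(1, sum(tab$counts_pos)), rep(0, sum(tab$counts_neg)))
    if (length(unique(ranks)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(labels, ranks,
                                                 direction = "<", quiet = TRUE)))
    expect_equal(roc_auc_ordinal(tab), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant to merging adjacent levels with equal LR", {
  tab <- diagnostic_table_counts(c("a", "b", "c"), c(2, 4, 10), c(4, 8, 5))
  # levels a and b have identical LR (0.5); merge them
  merged <- diagnostic_table_counts(c("ab", "c"), c(6, 10), c(12, 5))
  expect_equal(roc_auc_ordinal(tab), roc_auc_ordinal(merged))
})

test_that("Hanley-McNeil interval matches the formula and handles boundaries", {
  ci <- auc_ci(0.746, 53, 203)
  expect_equal(unname(ci["se"]), 0.04151, tolerance = 1e-4)
  # large balanced arms tighten around 0.5
  wide <- auc_ci(0.5, 50, 50)
  narrow <- auc_ci(0.5, 5000, 5000)
  expect_lt(narrow["upper"] - narrow["lower"], wide["upper"] - wide["lower"])
  expect_warning(deg <- auc_ci(1, 10, 10), "degenerate")
  expect_equal(unname(deg["upper"] - deg["lower"]), 0)
})

test_that("pooled two-sample proportion z-test", {
  r <- two_sample_proportion_test(0.4, 100, 0.4, 100)
  expect_equal(unname(r), c(0, 1))
  r2 <- two_sample_proportion_test(0.5, 100, 0.3, 100)
  expect_equal(unname(r2["z"]), 2.886751, tolerance = 1e-6)
  # oracle: z^2 equals the uncorrected chi-squared of prop.test
  chi <- prop.test(c(50, 30), c(100, 100), correct = FALSE)
  expect_equal(unname(r2["z"])^2, unname(chi$statistic), tolerance = 1e-10)
  expect_equal(unname(r2["p_value"]), chi$p.value, tolerance = 1e-10)
  # a student-vs-population sized comparison is decisively significant
  r3 <- two_sample_proportion_test(0.251, 399, 0.079, 200)
  expect_lt(r3["p_value"], 0.001)
  expect_error(two_sample_proportion_test(0, 10, 0, 10), "variance")
})

test_that("contingency test picks Fisher for sparse 2x2 and chi2 otherwise", {
  same <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(as.numeric(contingency_test(same, method = "fisher")), 1)
  # hypergeometric enumeration: the two extreme tables, 2/choose(20,10)
  sep <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(as.numeric(contingency_test(sep, method = "fisher")),
               2 / choose(20, 10), tolerance = 1e-12)
  # auto rule: Fisher when an expected 2x2 cell drops below 5
  expect_equal(attr(contingency_test(matrix(c(3, 0, 0, 3), 2)), "method"), "fisher")
  big <- matrix(c(40, 42, 38, 44), 2)
  expect_equal(attr(contingency_test(big), "method"), "chi2")
  # chi2 and Fisher agree closely when all expected counts are large
  huge <- matrix(c(420, 400, 380, 440), 2)
  expect_lt(abs(as.numeric(contingency_test(huge, "chi2")) -
                  as.numeric(contingency_test(huge, "fisher"))), 0.02)
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("evaluate_indicator ties everything together consistently", {
  co <- generate_category_cohort(category_model(), 20000, seed = 8)
  tab <- diagnostic_table(co$composite, co$depressed, levels = levels(co$composite))
  rep <- evaluate_indicator(tab)
  # internal identities, exact on the same table
  expect_equal(rep$posttest_pos, rep$ppv, tolerance = 1e-12)
  expect_equal(rep$posttest_neg, 1 - rep$npv, tolerance = 1e-12)
  expect_equal(rep$prevalence, rep$n_pos / (rep$n_pos + rep$n_neg))
  expect_true(all(rep$lr >= 0 | is.nan(rep$lr)))
  expect_lte(rep$auc[["lower"]], rep$auc[["auc"]])
  expect_lte(rep$auc[["auc"]], rep$auc[["upper"]])
  expect_output(print(rep), "likelihood ratios")
})

test_that("prevalence-weighted arm mixture recovers the pooled distribution", {
  set.seed(36)
  for (i in 1:20) {
    tab <- random_diag_table()
    n_pos <- sum(tab$counts_pos)
    n_neg <- sum(tab$counts_neg)
    prev <- n_pos / (n_pos + n_neg)
    pooled <- (tab$counts_pos + tab$counts_neg) / (n_pos + n_neg)
    mix <- prev * tab$counts_pos / n_pos + (1 - prev) * tab$counts_neg / n_neg
    expect_equal(mix, pooled, tolerance = 1e-12)
    expect_equal(sum(tab$counts_pos / n_pos), 1)
    expect_equal(sum(tab$counts_neg / n_neg), 1)
  }
})

test_that("analytic AUC from published summaries matches a simulated cohort", {
  model <- category_model()
  analytic <- auc_from_marginals(model$category_probs, model$lr, model$prevalence)
  co <- generate_category_cohort(model, 100000, seed = 9)
  tab <- diagnostic_table(co$composite, co$depressed, levels = levels(co$composite))
  expect_equal(roc_auc_ordinal(tab), analytic, tolerance = 0.01)
})

test_that("population comparison uses the packaged reference distribution", {
  ref <- general_population_reference()
  expect_setequal(ref$category,
                  c("vulnerable", "nonclass_normalSoC_highGHQ",
                    "nonclass_lowSoC_normalGHQ", "resilient"))
  props <- tibble::tibble(
    category = ref$category,
    n = c(100, 9, 176, 114),
    proportion = c(100, 9, 176, 114) / 399,
    lower = NA, upper = NA
  )
  cmp <- compare_populations(props, ref, population_n = 200)
  expect_lt(cmp$p_value[cmp$category == "vulnerable"], 0.001)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
})
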