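test_that("category model validates its inputs", {
  expect_s3_class(category_model(), "category_model")
  expect_error(category_model(prevalence = 0), "prevalence")
  expect_error(category_model(category_probs = c(
    vulnerable = 0.5, nonclass_normalSoC_highGHQ = 0.5,
    nonclass_lowSoC_normalGHQ = 0.5, resilient = 0.5)), "sum to 1")
  expect_error(category_model(lr = c(
    vulnerable = -1, nonclass_normalSoC_highGHQ = 0,
    nonclass_lowSoC_normalGHQ = 1, resilient = 1)), "non-negative")
})

test_that("category cohorts are seed-reproducible and leave global RNG alone", {
  model <- category_model()
  set.seed(99)
  before <- .Random.seed
  a <- generate_category_cohort(model, 500, seed = 5)
  expect_identical(before, .Random.seed)
  b <- generate_category_cohort(model, 500, seed = 5)
  expect_identical(a, b)
  c2 <- generate_category_cohort(model, 500, seed = 6)
  expect_false(identical(a$depressed, c2$depressed))
})

test_that("uninformative LRs give the prevalence in every category", {
  model <- category_model(lr = c(
    vulnerable = 1, nonclass_normalSoC_highGHQ = 1,
    nonclass_lowSoC_normalGHQ = 1, resilient = 1), prevalence = 0.3)
  co <- generate_category_cohort(model, 60000, seed = 7)
  rates <- tapply(co$depressed, co$composite, mean)
  moe <- 3 * sqrt(0.3 * 0.7 / table(co$composite))
  expect_true(all(abs(rates - 0.3) < moe))
})

test_that("category frequencies and marginal positive rate match the model", {
  model <- category_model()
  co <- generate_category_cohort(model, 200000, seed = 11)
  freq <- table(co$composite) / nrow(co)
  expect_true(all(abs(as.numeric(freq) - model$category_probs) < 0.005))
  # law of total probability for the marginal reference-positive rate
  p_dep <- bayes_posttest(model$prevalence, model$lr)
  expected <- sum(model$category_probs * p_dep)
  moe <- 3 * sqrt(expected * (1 - expected) / nrow(co))
  expect_lt(abs(mean(co$depressed) - expected), moe)
})

test_that("latent model validates thresholds and ranges hold in generated items", {
  expect_error(latent_model(thresholds = list(
    soc = c(1, 0, 2, 3, 4, 5), ghq = c(-1, 0, 1), bdi = c(-1, 0, 1),
    health = c(-1, 0, 1, 2))), "strictly increasing")
  co <- generate_item_cohort(latent_model(missing_rate = 0), 500, seed = 12)
  expect_false(anyNA(co[paste0("soc", 1:13)]))
  expect_true(all(as.matrix(co[paste0("soc", 1:13)]) %in% 1:7))
  expect_true(all(as.matrix(co[paste0("ghq", 1:12)]) %in% 0:3))
  expect_true(all(as.matrix(co[paste0("bdi", 1:9)]) %in% 0:3))
  expect_true(all(co$health %in% c("very good", "good", "fair", "bad", "very bad")))
  # missing-rate 0 -> complete matrix; positive rate -> holes appear
  co_miss <- generate_item_cohort(latent_model(missing_rate = 0.1), 500, seed = 12)
  expect_gt(sum(is.na(co_miss[paste0("soc", 1:13)])), 0)
})

test_that("factor loadings drive the SOC-GHQ score correlation", {
  zero <- latent_model(loadings = c(soc = 0, ghq = 0, bdi = 0, health = 0),
                       missing_rate = 0)
  s0 <- score_cohort(generate_item_cohort(zero, 2000, seed = 13))
  expect_lt(abs(cor(s0$soc_total, s0$ghq_total)), 0.07)
  strong <- latent_model(loadings = c(soc = 1.5, ghq = -1.5, bdi = -1, health = -1),
                         missing_rate = 0)
  s1 <- score_cohort(generate_item_cohort(strong, 2000, seed = 13))
  expect_lt(cor(s1$soc_total, s1$ghq_total), -0.4)
})

test_that("item cohorts are bit-reproducible under a fixed seed", {
  m <- latent_model()
  expect_identical(generate_item_cohort(m, 200, seed = 14),
                   generate_item_cohort(m, 200, seed = 14))
})

test_that("calibration hits the category targets and flags infeasible ones", {
  model <- calibrate_latent(seed = 2)
  cal <- attr(model, "calibration")
  expect_true(cal$success)
  expect_lte(cal$prop_error, 0.03)
  expect_lte(cal$lr_error, 0.4)
  expect_lte(abs(cal$achieved_props[["vulnerable"]] - 0.251), 0.03)
  # a degenerate one-category target is infeasible under the smooth model
  degenerate <- category_model(category_probs = c(
    vulnerable = 1, nonclass_normalSoC_highGHQ = 0,
    nonclass_lowSoC_normalGHQ = 0, resilient = 0))
  expect_warning(bad <- calibrate_latent(degenerate, n_calib = 4000, seed = 2),
                 "did not reach")
  expect_false(attr(bad, "calibration")$success)
})

test_that("an uninformative LR target recovers a near-zero depression slope", {
  flat <- category_model(lr = c(
    vulnerable = 1, nonclass_normalSoC_highGHQ = 1,
    nonclass_lowSoC_normalGHQ = 1, resilient = 1))
  model <- suppressWarnings(calibrate_latent(flat, n_calib = 8000, seed = 3))
  expect_lt(abs(model$loadings[["bdi"]]), 0.15)
  expect_lt(abs(model$depression_link[["slope"]]), 0.3)
  expect_lte(attr(model, "calibration")$lr_error, 0.4)
})
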