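# Synthetic cohorts at two fidelity levels: (a) category-level draws whose
# expectations match published composite-category marginals, likelihood
# ratios and prevalence exactly (for testing the diagnostics estimators);
# (b) item-level questionnaires from a single-factor latent-trait model (for
# end-to-end pipeline testing). Both are stand-ins for unavailable raw data,
# not models of any real population.

#' Category-level cohort model
#'
#' Defaults are the study conditions: composite-category marginals
#' 25.1 / 2.3 / 44.2 / 28.4 % (vulnerable / non-classifiable high-GHQ /
#' non-classifiable low-SOC / resilient), category likelihood ratios versus
#' depression \{2.61, 0, 1.05, 0.054\}, and depression prevalence 0.207
#' (implied by inverting the published positive post-test probability 0.405
#' through LR+ 2.61).
#'
#' @param category_probs named probabilities over the four composite levels,
#'   summing to 1.
#' @param lr named per-category likelihood ratios (>= 0).
#' @param prevalence pretest probability of the reference condition, in (0,1).
#' @return a \code{category_model} list.
#' @export
category_model <- function(
    category_probs = c(vulnerable = 0.251, nonclass_normalSoC_highGHQ = 0.023,
                       nonclass_lowSoC_normalGHQ = 0.442, resilient = 0.284),
    lr = c(vulnerable = 2.61, nonclass_normalSoC_highGHQ = 0,
           nonclass_lowSoC_normalGHQ = 1.05, resilient = 0.054),
    prevalence = 0.207) {
  stopifnot(setequal(names(category_probs), COMPOSITE_LEVELS),
            setequal(names(lr), COMPOSITE_LEVELS))
  category_probs <- category_probs[COMPOSITE_LEVELS]
  lr <- lr[COMPOSITE_LEVELS]
  if (abs(sum(category_probs) - 1) > 1e-9) {
    stop("category_probs must sum to 1", call. = FALSE)
  }
  if (any(category_probs < 0) || any(lr < 0)) {
    stop("probabilities and likelihood ratios must be non-negative", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)", call. = FALSE)
  structure(list(category_probs = category_probs, lr = lr,
                 prevalence = prevalence), class = "category_model")
}

#' Draw a category-level cohort
#'
#' Each subject's composite category is multinomial on the model's marginals;
#' the reference label is then Bernoulli with the category-conditional
#' posterior \eqn{P(D \mid c) = p\,LR_c / (p\,LR_c + 1 - p)}. By the law of
#' total probability the marginal positive rate converges to
#' \eqn{\sum_c P(c) P(D \mid c)}.
#'
#' @param model a [category_model()].
#' @param n cohort size.
#' @param seed integer seed; the draw is bit-reproducible and does not touch
#'   the caller's RNG state.
#' @return tibble with \code{id}, \code{composite} (factor) and
#'   \code{depressed} (logical).
#' @export
generate_category_cohort <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "category_model"), n >= 1)
  p_dep <- bayes_posttest(model$prevalence, model$lr)
  with_local_seed(seed, {
    cat_idx <- sample.int(4L, n, replace = TRUE, prob = model$category_probs)
    depressed <- stats::runif(n) < p_dep[cat_idx]
  })
  tibble::tibble(
    id = seq_len(n),
    composite = factor(COMPOSITE_LEVELS[cat_idx], levels = COMPOSITE_LEVELS),
    depressed = depressed
  )
}

#' Single-factor latent-trait model for item-level cohorts
#'
#' One latent "mental resilience" factor L ~ N(0,1) drives every item:
#' an item's underlying response is \eqn{y^* = a\,L + e}, \eqn{e \sim N(0,1)},
#' cut at the item block's thresholds. SOC items load positively, GHQ, BDI
#' and perceived-health items negatively. Thresholds are shared within an
#' instrument block (exchangeable items), which is sufficient to control the
#' score distributions the pipeline consumes. Depression and bad-health
#' labels are logistic in L.
#'
#' @param loadings named numeric: \code{soc}, \code{ghq}, \code{bdi},
#'   \code{health} per-item loadings.
#' @param thresholds named list of strictly increasing cutpoints:
#'   \code{soc} (6, levels 1-7), \code{ghq} (3, levels 0-3), \code{bdi}
#'   (3, levels 0-3), \code{health} (4, levels 1-5).
#' @param depression_link,health_link numeric \code{c(intercept, slope)} of a
#'   logistic model on L for the direct label columns.
#' @param missing_rate MCAR fraction applied to item and health columns.
#' @param prop_female probability a respondent is coded female.
#' @return a \code{latent_model} list.
#' @export
latent_model <- function(
    loadings = c(soc = 0.45, ghq = -0.45, bdi = -0.9, health = -0.8),
    thresholds = list(
      soc = seq(-2.0, 2.0, length.out = 6),
      ghq = c(-0.4, 0.55, 1.5),
      bdi = c(0.2, 1.3, 2.4),
      health = c(-1.3, 0.3, 1.6, 2.6)
    ),
    depression_link = c(intercept = -2.2, slope = -1.6),
    health_link = c(intercept = -0.7, slope = -1.2),
    missing_rate = 0.02,
    prop_female = 0.909) {
  for (nm in c("soc", "ghq", "bdi", "health")) {
    th <- thresholds[[nm]]
    if (is.null(th) || is.unsorted(th, strictly = TRUE)) {
      stop("thresholds$", nm, " must be strictly increasing", call. = FALSE)
    }
  }
  stopifnot(length(thresholds$soc) == 6, length(thresholds$ghq) == 3,
            length(thresholds$bdi) == 3, length(thresholds$health) == 4,
            missing_rate >= 0, missing_rate < 1)
  structure(list(loadings = loadings, thresholds = thresholds,
                 depression_link = depression_link, health_link = health_link,
                 missing_rate = missing_rate, prop_female = prop_female),
            class = "latent_model")
}

# Cut a matrix of latent responses (n x k) at `th`, returning ordinal codes
# starting at `base`.
cut_items <- function(ystar, th, base) {
  codes <- matrix(base + findInterval(ystar, th), nrow(ystar), ncol(ystar))
  codes
}

# Canonical SOC-13 reverse-keyed items: the generator emits these
# reverse-coded (8 - value) so that default scoring keying round-trips.
SOC_REVERSED <- c(1L, 2L, 3L, 7L, 10L)

#' Draw an item-level questionnaire cohort
#'
#' Simulates latent traits, item responses, demographic columns, direct
#' \code{depressed}/\code{bad_health} label columns (from the logistic
#' links), and applies an MCAR mask at the model's missing rate. The
#' returned table has the \code{item_matrix} schema (plus the label and
#' latent columns) and can be fed straight into [score_cohort()].
#'
#' @param model a [latent_model()].
#' @param n cohort size.
#' @param seed integer seed (bit-reproducible, local RNG).
#' @return an \code{item_matrix} tibble with extra columns \code{latent},
#'   \code{depressed}, \code{bad_health}.
#' @export
generate_item_cohort <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "latent_model"), n >= 1)
  with_local_seed(seed, {
    L <- stats::rnorm(n)
    soc <- cut_items(model$loadings[["soc"]] * L +
                       matrix(stats::rnorm(n * 13), n, 13), model$thresholds$soc, 1L)
    soc[, SOC_REVERSED] <- 8L - soc[, SOC_REVERSED]
    ghq <- cut_items(model$loadings[["ghq"]] * L +
                       matrix(stats::rnorm(n * 12), n, 12), model$thresholds$ghq, 0L)
    bdi <- cut_items(model$loadings[["bdi"]] * L +
                       matrix(stats::rnorm(n * 9), n, 9), model$thresholds$bdi, 0L)
    health_code <- drop(cut_items(matrix(model$loadings[["health"]] * L +
                                           stats::rnorm(n), n, 1),
                                  model$thresholds$health, 1L))
    depressed <- stats::runif(n) <
      stats::plogis(model$depression_link[[1]] + model$depression_link[[2]] * L)
    bad_health <- stats::runif(n) <
      stats::plogis(model$health_link[[1]] + model$health_link[[2]] * L)
    sex <- ifelse(stats::runif(n) < model$prop_female, "female", "male")
    age <- 18L + stats::rpois(n, 2.8)
    if (model$missing_rate > 0) {
      mask <- function(m) {
        m[matrix(stats::runif(length(m)) < model$missing_rate, nrow(m))] <- NA
        m
      }
      soc <- mask(soc); ghq <- mask(ghq); bdi <- mask(bdi)
      health_code[stats::runif(n) < model$missing_rate] <- NA
    }
  })
  out <- tibble::tibble(id = seq_len(n))
  out[paste0("ghq", 1:12)] <- as.data.frame(ghq)
  out[paste0("soc", 1:13)] <- as.data.frame(soc)
  out[paste0("bdi", 1:9)] <- as.data.frame(bdi)
  out$health <- PERCEIVED_HEALTH_LEVELS[health_code]
  out$sex <- sex
  out$age <- age
  out$latent <- L
  out$depressed <- depressed
  out$bad_health <- bad_health
  class(out) <- c("item_matrix", class(out))
  out
}

#' Calibrate the latent model to category-level targets
#'
#' Searches threshold shifts, loadings and the depression link so that a
#' cohort drawn from the returned model and pushed through the scoring
#' pipeline (fixed cutpoints: SOC > 65, GHQ > 4, BDI > 18) reproduces the
#' target composite-category proportions and the target vulnerable-level
#' likelihood ratio against the BDI-derived depression label.
#'
#' Search strategy (deterministic given \code{seed}; common random numbers
#' across candidates): a grid over the SOC/GHQ loading magnitude sets the
#' SOC-GHQ association; for each candidate, threshold shifts are bisected to
#' match the SOC-normal and GHQ-high marginals, and the best candidate
#' minimizes the maximum cell error. A second grid over the BDI loading,
#' with its threshold shift bisected to the target prevalence, matches the
#' vulnerable LR. The depression link is then recovered by logistic
#' regression of the BDI label on the latent.
#'
#' @param targets a [category_model()] with the target marginals, LRs and
#'   prevalence.
#' @param n_calib simulated cohort size per candidate evaluation.
#' @param search_budget maximum number of candidate evaluations.
#' @param seed integer seed.
#' @param tol_prop,tol_lr acceptance tolerances: max per-category proportion
#'   error and vulnerable-LR error.
#' @param missing_rate passed to the returned model (calibration itself uses
#'   complete data).
#' @return a calibrated \code{latent_model}; its \code{attr(, "calibration")}
#'   holds achieved proportions, LR, errors, evaluation count and a
#'   \code{success} flag. If tolerances are unreachable within budget, the
#'   best-found model is returned with \code{success = FALSE} and a warning.
#' @export
calibrate_latent <- function(targets = category_model(), n_calib = 20000L,
                             search_budget = 60L, seed = 1L,
                             tol_prop = 0.03, tol_lr = 0.4,
                             missing_rate = 0.02) {
  stopifnot(inherits(targets, "category_model"))
  probs <- targets$category_probs
  target_normal_soc <- probs[["resilient"]] + probs[["nonclass_normalSoC_highGHQ"]]
  target_high_ghq <- probs[["vulnerable"]] + probs[["nonclass_normalSoC_highGHQ"]]
  target_lr_vuln <- targets$lr[["vulnerable"]]
  prev <- targets$prevalence

  # Common random numbers: one set of latent traits and item noise reused for
  # every candidate, so the objective is deterministic and smooth in the
  # parameters.
  draws <- with_local_seed(child_seed(seed, 1L), list(
    L = stats::rnorm(n_calib),
    e_soc = matrix(stats::rnorm(n_calib * 13), n_calib, 13),
    e_ghq = matrix(stats::rnorm(n_calib * 12), n_calib, 12),
    e_bdi = matrix(stats::rnorm(n_calib * 9), n_calib, 9)
  ))
  evals <- 0L

  base <- latent_model(missing_rate = 0)
  soc_base <- base$thresholds$soc
  ghq_base <- base$thresholds$ghq
  bdi_base <- base$thresholds$bdi

  soc_totals <- function(a, shift) {
    items <- cut_items(a * draws$L + draws$e_soc, soc_base + shift, 1L)
    rowSums(items)   # orientation handled at emission; totals are keying-free
  }
  ghq_scores <- function(a, shift) {
    items <- cut_items(-a * draws$L + draws$e_ghq, ghq_base + shift, 0L)
    rowSums(items >= 2L)
  }
  bdi_totals <- function(b, shift) {
    rowSums(cut_items(-b * draws$L + draws$e_bdi, bdi_base + shift, 0L))
  }
  # Bisect `shift` so that mean(rate_fn(shift)) hits `target`; rate is
  # monotone decreasing in shift (raising thresholds lowers scores).
  bisect_shift <- function(rate_fn, target, lo = -4, hi = 4, iters = 25L) {
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (rate_fn(mid) > target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  # Stage 1: SOC/GHQ loading magnitude controls the 2x2 dependence.
  best <- NULL
  for (a in c(0.30, 0.40, 0.45, 0.50, 0.60, 0.75)) {
    if (evals >= search_budget) break
    s_soc <- bisect_shift(function(s) mean(soc_totals(a, s) > 65), target_normal_soc)
    s_ghq <- bisect_shift(function(s) mean(ghq_scores(a, s) > 4), target_high_ghq)
    evals <- evals + 1L
    soc_normal <- soc_totals(a, s_soc) > 65
    ghq_high <- ghq_scores(a, s_ghq) > 4
    cells <- c(
      vulnerable = mean(!soc_normal & ghq_high),
      nonclass_normalSoC_highGHQ = mean(soc_normal & ghq_high),
      nonclass_lowSoC_normalGHQ = mean(!soc_normal & !ghq_high),
      resilient = mean(soc_normal & !ghq_high)
    )[COMPOSITE_LEVELS]
    err <- max(abs(cells - probs))
    if (is.null(best) || err < best$err) {
      best <- list(a = a, s_soc = s_soc, s_ghq = s_ghq, cells = cells, err = err,
                   soc_normal = soc_normal, ghq_high = ghq_high)
    }
  }

  # Stage 2: BDI loading controls the vulnerable-level LR (monotone
  # increasing in the loading magnitude); its threshold shift pins the
  # at-risk prevalence. Bisect the loading to the target LR.
  vuln <- !best$soc_normal & best$ghq_high
  eval_b <- function(b) {
    s_bdi <- bisect_shift(function(s) mean(bdi_totals(b, s) > 18), prev)
    dep <- bdi_totals(b, s_bdi) > 18
    p_neg <- mean(vuln[!dep])
    lr_v <- if (p_neg == 0) Inf else mean(vuln[dep]) / p_neg
    list(b = b, s_bdi = s_bdi, lr = lr_v, dep = dep)
  }
  lo_b <- eval_b(0)
  hi_b <- eval_b(2.5)
  evals <- evals + 2L
  best_b <- if (abs(lo_b$lr - target_lr_vuln) < abs(hi_b$lr - target_lr_vuln)) lo_b else hi_b
  if (lo_b$lr < target_lr_vuln && target_lr_vuln < hi_b$lr) {
    while (evals < search_budget && hi_b$b - lo_b$b > 0.01) {
      mid <- eval_b((lo_b$b + hi_b$b) / 2)
      evals <- evals + 1L
      if (mid$lr < target_lr_vuln) lo_b <- mid else hi_b <- mid
      if (abs(mid$lr - target_lr_vuln) < abs(best_b$lr - target_lr_vuln)) best_b <- mid
    }
  }

  # Depression link recovered from the calibrated BDI dichotomy.
  # suppress separation warnings: near-degenerate targets legitimately push
  # the fitted probabilities to 0/1
  link <- suppressWarnings(stats::glm(best_b$dep ~ draws$L, family = stats::binomial()))
  model <- latent_model(
    loadings = c(soc = best$a, ghq = -best$a, bdi = -best_b$b, health = -0.8),
    thresholds = list(
      soc = soc_base + best$s_soc,
      ghq = ghq_base + best$s_ghq,
      bdi = bdi_base + best_b$s_bdi,
      health = base$thresholds$health
    ),
    depression_link = c(intercept = unname(stats::coef(link)[1]),
                        slope = unname(stats::coef(link)[2])),
    health_link = base$health_link,
    missing_rate = missing_rate
  )
  success <- best$err <= tol_prop && abs(best_b$lr - target_lr_vuln) <= tol_lr
  attr(model, "calibration") <- list(
    achieved_props = best$cells,
    prop_error = best$err,
    achieved_lr_vulnerable = best_b$lr,
    lr_error = abs(best_b$lr - target_lr_vuln),
    evaluations = evals,
    n_calib = n_calib,
    success = success
  )
  if (!success) {
    warning(sprintf(
      "calibration did not reach tolerances (max proportion error %.3f, LR error %.3f); returning best-found model",
      best$err, abs(best_b$lr - target_lr_vuln)), call. = FALSE)
  }
  model
}
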