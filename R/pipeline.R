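#' Pipeline run configuration
#'
#' Bundles every tunable the score -> classify -> evaluate pipeline uses.
#' Defaults are the study rules: GHQ distress strictly above 4, SOC normal
#' strictly above the fixed upper-tertile cut of 65, BDI at-risk strictly
#' over 18, 95% intervals.
#'
#' @param ghq_cutoff GHQ-12 distress threshold (high = strictly above).
#' @param soc_cutpoint fixed SOC upper-tertile cut (normal = strictly above).
#' @param tertile \code{"fixed"} or \code{"empirical"} (recompute the cut
#'   from the analyzed cohort).
#' @param reference reference standard: \code{"bdi"} (at-risk depression,
#'   total > 18) or \code{"health"} (fair-or-worse perceived health).
#' @param ci_level confidence level for intervals.
#' @param soc_reversed_items SOC-13 reversal keying.
#' @param min_answer_fraction respondents answering less than this fraction
#'   of the questionnaire are excluded (with a logged reason).
#' @param seed recorded in the run manifest.
#' @return a \code{run_config} list.
#' @export
pipeline_config <- function(ghq_cutoff = 4L, soc_cutpoint = 65,
                            tertile = c("fixed", "empirical"),
                            reference = c("bdi", "health"),
                            ci_level = 0.95,
                            soc_reversed_items = c(1L, 2L, 3L, 7L, 10L),
                            min_answer_fraction = 0.25,
                            seed = 1L) {
  tertile <- match.arg(tertile)
  reference <- match.arg(reference)
  stopifnot(ghq_cutoff >= 0, ghq_cutoff <= 12, soc_cutpoint >= 13,
            soc_cutpoint <= 91, ci_level > 0, ci_level < 1,
            min_answer_fraction >= 0, min_answer_fraction <= 1)
  structure(list(
    ghq_cutoff = ghq_cutoff, soc_cutpoint = soc_cutpoint, tertile = tertile,
    reference = reference, ci_level = ci_level,
    soc_reversed_items = soc_reversed_items,
    min_answer_fraction = min_answer_fraction, seed = seed
  ), class = "run_config")
}

#' Run the full screening pipeline
#'
#' Reads (or accepts) an item-level cohort, applies the low-response
#' exclusion rule, scores all instruments, classifies the composite
#' indicator, summarizes category prevalences with Wilson intervals,
#' evaluates the indicator against the configured reference standard, and
#' reports per-variable missingness. The run is a pure function of
#' (input, config): rerunning with the same pair yields byte-identical
#' artifacts, recorded in a machine-readable manifest.
#'
#' @param input path to an item-level CSV (see [read_item_matrix()]) or an
#'   \code{item_matrix}.
#' @param config a [pipeline_config()].
#' @param output_dir if non-NULL, artifacts are written there:
#'   \code{scored.csv}, \code{summary.csv}, \code{report.json},
#'   \code{exclusions.csv}, \code{missingness.csv}, \code{manifest.json}.
#' @return (invisibly) a list: \code{scored} (classified cohort),
#'   \code{summary} (category proportions), \code{report} (eval_report),
#'   \code{missingness}, \code{exclusions}, \code{manifest},
#'   \code{soc_cutpoint}.
#' @export
run_pipeline <- function(input, config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  items <- if (is.character(input)) read_item_matrix(input) else input
  if (!inherits(items, "item_matrix")) items <- as_item_matrix(items)

  # Exclusion rule: drop respondents who answered less than the configured
  # fraction of the questionnaire (items + health + sex + age).
  answer_cols <- c(paste0("ghq", 1:12), paste0("soc", 1:13), paste0("bdi", 1:9),
                   "health", "sex", "age")
  answered <- rowMeans(!is.na(as.data.frame(items)[answer_cols]))
  excluded <- answered < config$min_answer_fraction
  exclusions <- tibble::tibble(
    id = items$id[excluded],
    reason = sprintf("answered %.0f%% of questions (below %.0f%% minimum)",
                     100 * answered[excluded], 100 * config$min_answer_fraction)
  )
  analyzed <- items[!excluded, , drop = FALSE]
  if (nrow(analyzed) == 0) stop("no respondents left after exclusions", call. = FALSE)

  scored <- score_cohort(analyzed, soc_reversed_items = config$soc_reversed_items,
                         ghq_cutoff = config$ghq_cutoff)
  scored <- classify_cohort(scored, tertile = config$tertile,
                            soc_cutpoint = config$soc_cutpoint)
  summary_tbl <- category_proportions(scored, ci_level = config$ci_level)

  reference <- switch(config$reference,
    bdi = scored$bdi_at_risk,
    health = ifelse(is.na(scored$health_cat), NA, scored$health_cat == "bad")
  )
  dtab <- diagnostic_table(scored$composite, reference, levels = COMPOSITE_LEVELS)
  # tiny cohorts can leave a reference arm empty; the run still completes,
  # just without the diagnostic evaluation
  report <- if (sum(dtab$counts_pos) == 0 || sum(dtab$counts_neg) == 0) {
    warning("a reference arm is empty; diagnostic evaluation skipped",
            call. = FALSE)
    NULL
  } else {
    evaluate_indicator(dtab, ci_level = config$ci_level)
  }
  miss <- missing_rate_report(analyzed[answer_cols])

  manifest <- list(
    package = "resilscreen",
    version = as.character(utils::packageVersion("resilscreen")),
    config = unclass(config),
    config_md5 = unname(config_md5(config)),
    n_input = nrow(items),
    n_excluded = sum(excluded),
    n_analyzed = nrow(analyzed),
    soc_cutpoint_used = attr(scored, "soc_cutpoint")
  )

  out <- list(scored = scored, summary = summary_tbl, report = report,
              missingness = miss, exclusions = exclusions, manifest = manifest,
              soc_cutpoint = attr(scored, "soc_cutpoint"))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(scored, file.path(output_dir, "scored.csv"), row.names = FALSE)
    write.csv(summary_tbl, file.path(output_dir, "summary.csv"), row.names = FALSE)
    write.csv(exclusions, file.path(output_dir, "exclusions.csv"), row.names = FALSE)
    write.csv(miss, file.path(output_dir, "missingness.csv"), row.names = FALSE)
    report_json <- if (is.null(report)) {
      list(note = "diagnostic evaluation skipped: a reference arm was empty")
    } else {
      report_as_list(report)
    }
    jsonlite::write_json(report_json, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

# Stable fingerprint of a config for the run manifest.
config_md5 <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  tools::md5sum(f)
}

# Flatten an eval_report for JSON serialization.
report_as_list <- function(report) {
  list(
    prevalence = report$prevalence,
    lr = as.list(report$lr),
    lr_pos = report$lr_pos,
    lr_neg = report$lr_neg,
    posttest_pos = report$posttest_pos,
    posttest_neg = report$posttest_neg,
    ppv = report$ppv,
    npv = report$npv,
    auc = as.list(report$auc),
    ci_level = report$ci_level,
    n_pos = report$n_pos,
    n_neg = report$n_neg
  )
}
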