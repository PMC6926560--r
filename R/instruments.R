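#' Score the GHQ-12 with binary (0-0-1-1) scoring
#'
#' Each of the 12 items is answered on a 4-point Likert scale coded 0-3,
#' oriented so that higher responses indicate more of the symptom. GHQ
#' "simplest" scoring assigns 1 to a present symptom (response of 2 or 3) and
#' 0 otherwise, so the total ranges 0-12. The score is missing if any item is
#' missing (strict available-case rule; no imputation).
#'
#' @param items numeric vector (one respondent) or matrix/data frame
#'   (respondents x 12 items) of responses in \code{0:3}, \code{NA} = missing.
#' @param id optional respondent identifiers used in validation messages.
#' @return integer vector of totals in \code{0:12}, \code{NA} where any item
#'   is missing.
#' @examples
#' score_ghq12(rep(0, 12))              # 0
#' score_ghq12(rep(3, 12))              # 12
#' score_ghq12(c(0, 1, 2, 3, 0, 1, 2, 3, 0, 1, 2, 3))  # 6
#' @export
score_ghq12 <- function(items, id = NULL) {
  m <- as_item_block(items, 12L, "GHQ-12")
  check_range(m, 0L, 3L, "GHQ-12 item response", id = rep(id %||% seq_len(nrow(m)), ncol(m)))
  tot <- rowSums(m >= 2L)
  tot[!complete.cases(m)] <- NA
  as.integer(tot)
}

#' Classify psychological distress from a GHQ-12 total
#'
#' High distress is a total strictly above 4 (equivalently, 5 points or more).
#'
#' @param ghq_total integer vector of GHQ-12 totals (0-12); \code{NA} allowed.
#' @param cutoff distress threshold; "high" means strictly above it.
#' @return character vector \code{"high"}/\code{"normal"}, \code{NA} propagated.
#' @export
classify_distress <- function(ghq_total, cutoff = 4L) {
  check_range(ghq_total, 0L, 12L, "GHQ-12 total")
  ifelse(is.na(ghq_total), NA_character_, ifelse(ghq_total > cutoff, "high", "normal"))
}

#' Score the 13-item Sense of Coherence scale (SOC-13)
#'
#' Items are answered on a 7-point scale coded 1-7; reverse-keyed items are
#' mapped \eqn{r \to 8 - r} before summing, so the total ranges 13-91 with
#' higher scores indicating greater sense of coherence. The default reversal
#' set is the canonical SOC-13 keying (items 1, 2, 3, 7, 10); pass
#' \code{reversed_items = integer(0)} if responses are already fully oriented.
#' A total is missing if any item is missing.
#'
#' @param items numeric vector or respondents x 13 matrix of responses in
#'   \code{1:7}.
#' @param reversed_items integer indices (1-13) of reverse-keyed items.
#' @param id optional respondent identifiers for validation messages.
#' @return integer vector of totals in 13-91, \code{NA} where incomplete.
#' @examples
#' score_soc13(rep(1, 13), reversed_items = integer(0))  # 13
#' score_soc13(rep(7, 13), reversed_items = integer(0))  # 91
#' @export
score_soc13 <- function(items, reversed_items = c(1L, 2L, 3L, 7L, 10L), id = NULL) {
  m <- as_item_block(items, 13L, "SOC-13")
  check_range(m, 1L, 7L, "SOC-13 item response", id = rep(id %||% seq_len(nrow(m)), ncol(m)))
  if (length(reversed_items)) {
    stopifnot(all(reversed_items %in% 1:13))
    m[, reversed_items] <- 8L - m[, reversed_items]
  }
  tot <- rowSums(m)
  tot[!complete.cases(m)] <- NA
  as.integer(tot)
}

#' Score the 9-item Beck Depression Inventory short form
#'
#' The total is the plain item sum. Bands: 9 or below = none, 10-18 = mild,
#' 19-25 = moderate, above 25 = severe; the at-risk dichotomy (reference
#' standard for the composite indicator) pools moderate and severe, i.e. a
#' total strictly over 18 points.
#'
#' @param items numeric vector or respondents x 9 matrix of item responses
#'   (non-negative integers).
#' @param item_max maximum per-item response used for validation (default 3).
#' @param id optional respondent identifiers.
#' @return a [tibble::tibble] with columns \code{bdi_total}, \code{bdi_band}
#'   (factor none < mild < moderate < severe) and \code{bdi_at_risk} (logical).
#' @export
score_bdi9 <- function(items, item_max = 3L, id = NULL) {
  m <- as_item_block(items, 9L, "BDI-9")
  check_range(m, 0L, item_max, "BDI-9 item response", id = rep(id %||% seq_len(nrow(m)), ncol(m)))
  tot <- rowSums(m)
  tot[!complete.cases(m)] <- NA
  band <- bdi_band(tot)
  tibble::tibble(
    bdi_total = as.integer(tot),
    bdi_band = band,
    bdi_at_risk = !is.na(tot) & tot > 18L
  )
}

# Band a BDI total; a score of exactly 9 falls in "none" (it is below the
# mild band's floor of 10).
bdi_band <- function(total) {
  factor(
    ifelse(is.na(total), NA_character_,
      ifelse(total <= 9, "none",
        ifelse(total <= 18, "mild",
          ifelse(total <= 25, "moderate", "severe")))),
    levels = c("none", "mild", "moderate", "severe"), ordered = TRUE
  )
}

#' Dichotomize 5-level perceived health
#'
#' "good" pools the top two levels (very good, good); "bad" pools fair and
#' below.
#'
#' @param perceived_health character/factor with levels "very good", "good",
#'   "fair", "bad", "very bad", or integer codes 1-5 in that order.
#' @return character vector \code{"good"}/\code{"bad"}, \code{NA} propagated.
#' @export
dichotomize_health <- function(perceived_health) {
  x <- perceived_health
  if (is.numeric(x)) {
    check_range(x, 1L, 5L, "perceived health code")
    x <- PERCEIVED_HEALTH_LEVELS[x]
  }
  x <- as.character(x)
  bad_lab <- !is.na(x) & !(x %in% PERCEIVED_HEALTH_LEVELS)
  if (any(bad_lab)) {
    stop("unknown perceived-health level: ", x[bad_lab][1], call. = FALSE)
  }
  ifelse(is.na(x), NA_character_, ifelse(x %in% c("very good", "good"), "good", "bad"))
}

#' Read an item-level questionnaire table
#'
#' Expects a delimited text file with header columns \code{id},
#' \code{ghq1..ghq12}, \code{soc1..soc13}, \code{bdi1..bdi9}, \code{health},
#' \code{sex}, \code{age}; empty cells (or \code{na_strings}) mark missing
#' responses. Respondent ids must be unique.
#'
#' @param path CSV file path.
#' @param na_strings values treated as missing.
#' @return an \code{item_matrix}: a tibble with the schema above and integer
#'   item columns.
#' @export
read_item_matrix <- function(path, na_strings = c("", "NA")) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = na_strings,
                 check.names = FALSE)
  as_item_matrix(df)
}

#' Validate a raw data frame as an item-level questionnaire table
#'
#' @param df data frame with the schema described in [read_item_matrix()].
#' @return the validated \code{item_matrix} tibble.
#' @export
as_item_matrix <- function(df) {
  needed <- c("id", paste0("ghq", 1:12), paste0("soc", 1:13), paste0("bdi", 1:9),
              "health", "sex", "age")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("item matrix lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("respondent ids are not unique", call. = FALSE)
  out <- tibble::as_tibble(df[needed])
  for (block in list(c("ghq", 0L, 3L, 12L), c("soc", 1L, 7L, 13L), c("bdi", 0L, 3L, 9L))) {
    cols <- paste0(block[1], seq_len(as.integer(block[4])))
    m <- as.matrix(out[cols])
    storage.mode(m) <- "integer"
    check_range(m, as.integer(block[2]), as.integer(block[3]),
                paste0(toupper(block[1]), " item response"),
                id = rep(out$id, length(cols)))
    out[cols] <- as.data.frame(m)
  }
  if (any(!is.na(out$age) & (out$age < 1 | out$age != floor(out$age)))) {
    stop("age must be a positive integer", call. = FALSE)
  }
  class(out) <- c("item_matrix", class(out))
  out
}

#' Score a full cohort
#'
#' Applies all instrument scorers to an item matrix and appends scale totals,
#' dichotomies and BDI bands. Downstream composite classification is done by
#' [classify_cohort()].
#'
#' @param items an \code{item_matrix} (see [read_item_matrix()]).
#' @param soc_reversed_items reversal keying passed to [score_soc13()];
#'   default is the canonical SOC-13 reversed set. The synthetic item
#'   generator emits reverse-coded responses on the same items, so defaults
#'   round-trip.
#' @param ghq_cutoff distress threshold (strictly above = high).
#' @return a \code{scored_cohort} tibble: the input id/sex/age plus
#'   \code{soc_total}, \code{ghq_total}, \code{bdi_total}, \code{bdi_band},
#'   \code{bdi_at_risk}, \code{distress}, \code{health_cat}.
#' @export
score_cohort <- function(items, soc_reversed_items = c(1L, 2L, 3L, 7L, 10L),
                         ghq_cutoff = 4L) {
  stopifnot(inherits(items, "item_matrix") || is.data.frame(items))
  if (!inherits(items, "item_matrix")) items <- as_item_matrix(items)
  ghq <- score_ghq12(as.matrix(items[paste0("ghq", 1:12)]), id = items$id)
  soc <- score_soc13(as.matrix(items[paste0("soc", 1:13)]),
                     reversed_items = soc_reversed_items, id = items$id)
  bdi <- score_bdi9(as.matrix(items[paste0("bdi", 1:9)]), id = items$id)
  out <- tibble::tibble(
    id = items$id,
    sex = items$sex,
    age = items$age,
    soc_total = soc,
    ghq_total = ghq,
    bdi_total = bdi$bdi_total,
    bdi_band = bdi$bdi_band,
    bdi_at_risk = ifelse(is.na(bdi$bdi_total), NA, bdi$bdi_at_risk),
    distress = classify_distress(ghq, cutoff = ghq_cutoff),
    health_cat = dichotomize_health(items$health)
  )
  class(out) <- c("scored_cohort", class(out))
  out
}

# Coerce a vector (single respondent) or rectangular input into an n x k
# integer matrix for one instrument block.
as_item_block <- function(items, k, what) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.null(dim(items))) {
    if (length(items) != k) {
      stop(sprintf("%s expects %d items, got %d", what, k, length(items)), call. = FALSE)
    }
    items <- matrix(items, nrow = 1)
  }
  if (ncol(items) != k) {
    stop(sprintf("%s expects %d item columns, got %d", what, k, ncol(items)), call. = FALSE)
  }
  storage.mode(items) <- "double"
  items
}
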