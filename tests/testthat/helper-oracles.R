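# Independent brute-force oracles and small fixture builders used across the
# suite. These stay deliberately naive: per-subject expansion and pairwise
# enumeration, never the grouped-count formulas they are meant to check.

# AUC by exhaustive pairwise comparison over all (positive, negative) subject
# pairs, on ordinal ranks.
brute_force_auc <- function(counts_pos, counts_neg) {
  pos_ranks <- rep(seq_along(counts_pos), counts_pos)
  neg_ranks <- rep(seq_along(counts_neg), counts_neg)
  cmp <- outer(pos_ranks, neg_ranks, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Per-level LR from first principles: conditional level frequencies in each
# arm, one division per level.
brute_force_lr <- function(counts_pos, counts_neg) {
  sapply(seq_along(counts_pos), function(i) {
    (counts_pos[i] / sum(counts_pos)) / (counts_neg[i] / sum(counts_neg))
  })
}

# Random diagnostic table with <= max_total subjects and both arms non-empty.
random_diag_table <- function(n_levels = sample(2:5, 1), max_total = 200) {
  repeat {
    total <- sample(4:max_total, 1)
    n_pos <- sample(seq_len(total - 1), 1)
    pos <- as.integer(table(factor(sample.int(n_levels, n_pos, replace = TRUE),
                                   levels = seq_len(n_levels))))
    neg <- as.integer(table(factor(sample.int(n_levels, total - n_pos, replace = TRUE),
                                   levels = seq_len(n_levels))))
    if (sum(pos) > 0 && sum(neg) > 0) {
      return(diagnostic_table_counts(paste0("L", seq_len(n_levels)), pos, neg))
    }
  }
}

# Minimal complete item-matrix row used to build tiny cohorts by hand.
blank_respondent <- function(id) {
  row <- as.list(c(
    setNames(rep(0L, 12), paste0("ghq", 1:12)),
    setNames(rep(4L, 13), paste0("soc", 1:13)),
    setNames(rep(0L, 9), paste0("bdi", 1:9))
  ))
  c(list(id = id), row, list(health = "good", sex = "female", age = 21L))
}
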