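# shared fixture builders -------------------------------------------------

# tiny counts table with fixed values
tiny_counts <- function() {
  m <- matrix(c(2, 3, 5,
                1, 0, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("gA", "gB", "gC")))
  genus_table(m, kind = "counts")
}

# random counts table, seeded
random_counts <- function(n = 8, p = 12, seed = 1, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = max_count / 4), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("g%02d", seq_len(p))))
  m[1, ] <- m[1, ] + 1  # guard against all-zero rows
  genus_table(m, kind = "counts")
}

# metadata for a vector of sample ids cycling through the six stages
cycling_metadata <- function(ids, stages = stage6_levels()) {
  cohort_metadata(data.frame(sample_id = ids,
                             stage6 = rep_len(stages, length(ids)),
                             stringsAsFactors = FALSE))
}

# metadata assigning the first half of ids to one stage, rest to another
split_metadata <- function(ids, stage_a = "normal", stage_b = "crc_early") {
  half <- ceiling(length(ids) / 2)
  cohort_metadata(data.frame(
    sample_id = ids,
    stage6 = c(rep(stage_a, half), rep(stage_b, length(ids) - half)),
    stringsAsFactors = FALSE))
}

# brute-force two-sided exact Mann-Whitney p by full enumeration of all
# choose(n1+n2, n1) assignments of the pooled ranks -- the independent
# oracle for the DP implementation
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small synthetic config: 3 drivers + K equal blocks of `size` genera
block_config <- function(K = 3, size = 6, n_per_cell = 10, seed_names = "G",
                         noise_sd = 1, depth = 50000, ...) {
  genera <- sprintf("%s%02d", seed_names, seq_len(K * size))
  blocks <- split(genera, rep(seq_len(K), each = size))
  names(blocks) <- paste0("blk", seq_len(K))
  panel <- c("Bacteroides", "Prevotella", "Escherichia", genera)
  synthetic_config(panel, blocks, 0.8, "blk1", noise_sd = noise_sd,
                   depth = depth, n_per_cell = n_per_cell, ...)
}
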