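test_that("correlation_matrix matches a pairwise oracle", {
  tab <- to_relative(random_counts(n = 15, p = 10, seed = 14))
  r <- correlation_matrix(tab, method = "spearman")
  m <- unclass(tab)
  for (i in 1:9) for (j in (i + 1):10) {
    oracle <- cor(rank(m[, i]), rank(m[, j]))  # Spearman via rank-Pearson
    expect_equal(r[i, j], oracle, tolerance = 1e-12)
  }
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 10))
})

test_that("duplicated and reversed genera hit the correlation bounds", {
  m <- cbind(g1 = c(1, 4, 2, 8, 5), g2 = c(1, 4, 2, 8, 5),
             g3 = -c(1, 4, 2, 8, 5) + 10)
  rownames(m) <- sprintf("s%d", 1:5)
  tab <- genus_table(m / rowSums(m), "relative")
  r <- correlation_matrix(tab, method = "spearman")
  expect_equal(r["g1", "g2"], 1)
  expect_equal(r["g1", "g3"], -1)
  # a genus constant after closure has no defined correlation
  x <- c(0.1, 0.2, 0.3, 0.25, 0.15)
  m2 <- cbind(g1 = x, g2 = 0.75 - x, g4 = rep(0.25, 5))
  rownames(m2) <- sprintf("s%d", 1:5)
  tab2 <- genus_table(m2, "relative")
  expect_error(correlation_matrix(tab2, genus_subset = c("g1", "g4")),
               "g4")
})

test_that("spearman correlations agree between counts and closures at equal depth", {
  set.seed(3)
  counts <- matrix(rpois(20 * 6, 30), 20, 6,
                   dimnames = list(sprintf("s%d", 1:20),
                                   sprintf("g%d", 1:6)))
  counts <- round(counts / rowSums(counts) * 1000)  # equalise depths
  keep <- rowSums(counts) == 1000
  counts <- counts[keep, , drop = FALSE]
  tabc <- genus_table(counts, "counts")
  r1 <- correlation_matrix(tabc, method = "spearman")
  r2 <- correlation_matrix(to_relative(tabc), method = "spearman")
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("define_cags separates perfect blocks and respects fixed k", {
  r <- matrix(0, 6, 6,
              dimnames = list(sprintf("g%d", 1:6), sprintf("g%d", 1:6)))
  r[1:3, 1:3] <- 1
  r[4:6, 4:6] <- 1
  part <- define_cags(r, k = 2)
  expect_identical(attr(part, "K"), 2L)
  expect_length(unique(part$cag[1:3]), 1)
  expect_length(unique(part$cag[4:6]), 1)
  expect_false(part$cag[1] == part$cag[4])
  expect_error(define_cags(r, k = 7), "exceeds")
})

test_that("degenerate equal-correlation input falls back to k = 2", {
  r <- matrix(0.5, 5, 5,
              dimnames = list(letters[1:5], letters[1:5]))
  diag(r) <- 1
  expect_warning(part <- define_cags(r), "degenerate")
  expect_identical(attr(part, "K"), 2L)
})

test_that("partitions are invariant under genus permutation", {
  co <- generate_cohort(block_config(K = 3, size = 5, n_per_cell = 15),
                        seed = 17)
  rel <- to_relative(co$table)
  gs <- setdiff(colnames(rel), enterotype_drivers())
  r <- correlation_matrix(rel, genus_subset = gs)
  p1 <- define_cags(r, k = 3)
  perm <- sample(gs)
  p2 <- define_cags(r[perm, perm], k = 3)
  m1 <- setNames(p1$cag, p1$genus)
  m2 <- setNames(p2$cag, p2$genus)
  expect_equal(adjusted_rand_index(m1[gs], m2[gs]), 1)
})

test_that("silhouette scan recovers planted blocks", {
  # scaled-down CAG recovery (n ~ 200, ARI run in acceptance at defaults)
  co <- generate_cohort(block_config(K = 5, size = 6, n_per_cell = 22),
                        seed = 42)
  rel <- to_relative(co$table)
  gs <- setdiff(colnames(rel), enterotype_drivers())
  part <- define_cags(correlation_matrix(rel, genus_subset = gs))
  expect_identical(attr(part, "K"), 5L)
  tg <- co$truth$genera
  truth <- tg$block[match(part$genus, tg$genus)]
  expect_gte(adjusted_rand_index(part$cag, truth), 0.9)
})

test_that("cag_abundance sums member genera and conserves mass", {
  m <- rbind(s1 = c(0.2, 0.3, 0.5), s2 = c(0.6, 0.1, 0.3))
  colnames(m) <- c("g1", "g2", "g3")
  tab <- genus_table(m, "relative")
  part <- structure(data.frame(genus = c("g1", "g2", "g3"),
                               cag = c(1L, 1L, 2L)),
                    K = 2L, class = c("cag_partition", "data.frame"))
  prof <- cag_abundance(tab, part)
  expect_equal(prof["s1", ], c(CAG1 = 0.5, CAG2 = 0.5))
  expect_equal(unname(rowSums(prof)), c(1, 1))
  # missing genus errors
  part_bad <- structure(data.frame(genus = "gX", cag = 1L), K = 1L,
                        class = c("cag_partition", "data.frame"))
  expect_error(cag_abundance(tab, part_bad), "missing")
  # exact conservation on a random cohort
  rt <- to_relative(random_counts(n = 10, p = 9, seed = 23))
  rp <- define_cags(correlation_matrix(rt), k = 3)
  profs <- cag_abundance(rt, rp)
  expect_equal(rowSums(profs), rowSums(unclass(rt)[, rp$genus]),
               tolerance = 1e-12)
})

test_that("planted effect blocks are flagged at the CAG level", {
  # scaled to 3 seeds; 100-seed rates measured in acceptance
  up_ok <- 0; dn_ok <- 0
  for (s in 1:3) {
    co <- generate_cohort(default_config(n_per_cell = 20), seed = 400 + s)
    rel <- to_relative(co$table)
    gs <- setdiff(colnames(rel), enterotype_drivers())
    part <- define_cags(correlation_matrix(rel, genus_subset = gs))
    prof <- cag_abundance(rel, part)
    cmp <- compare_cag_abundance(prof, co$metadata,
                                 comparisons = list(c("normal", "cancer")))
    tg <- co$truth$genera
    cag_of <- function(block) {
      ids <- part$cag[match(tg$genus[!is.na(tg$block) & tg$block == block],
                            part$genus)]
      paste0("CAG", names(which.max(table(ids))))
    }
    up <- cmp[cmp$cag == cag_of("pathogen"), ]
    dn <- cmp[cmp$cag == cag_of("butyrate"), ]
    if (up$significant && up$direction == "up_in_second") up_ok <- up_ok + 1
    if (dn$significant && dn$direction == "down_in_second") dn_ok <- dn_ok + 1
  }
  expect_gte(up_ok, 2)
  expect_gte(dn_ok, 2)
})

test_that("combination selection is deterministic with a documented tie-break", {
  co <- generate_cohort(default_config(n_per_cell = 8), seed = 51)
  rel <- to_relative(co$table)
  single <- select_training_combination(rel, co$metadata,
                                        combinations = list(
                                          c("normal", "cancer")))
  expect_identical(single$ranking$combination, "cancer+normal")
  expect_s3_class(single$winner, "cag_partition")
  expect_error(select_training_combination(rel, co$metadata,
                                           combinations = list()),
               "empty combination")
  two <- select_training_combination(rel, co$metadata)
  two_again <- select_training_combination(rel, co$metadata)
  expect_identical(two$ranking, two_again$ranking)
  expect_false(is.unsorted(rev(two$ranking$score)))
})

test_that("training on cancer-containing samples beats adenoma-only when blocks are silent in adenoma", {
  blocks <- lapply(1:4, function(i) sprintf("%s%02d", LETTERS[i], 1:8))
  names(blocks) <- paste0("b", 1:4)
  panel <- c("Bacteroides", "Prevotella", "Escherichia",
             unlist(blocks, use.names = FALSE))
  ge <- matrix(0, length(panel), 3,
               dimnames = list(panel, group3_levels()))
  ge[blocks$b2, "cancer"] <- 2
  ge[blocks$b3, "cancer"] <- -2
  cfg <- synthetic_config(panel, blocks, 0.8, "b1", group_effects = ge,
                          n_per_cell = 20,
                          block_groups = lapply(blocks, function(b)
                            c("normal", "cancer")))
  wins <- 0
  for (s in 1:5) {
    co <- generate_cohort(cfg, seed = 500 + s)
    rel <- to_relative(co$table)
    sel <- select_training_combination(
      rel, co$metadata,
      combinations = list("adenoma", c("normal", "cancer")))
    sc <- setNames(sel$ranking$score, sel$ranking$combination)
    if (sc["cancer+normal"] > sc["adenoma"]) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("null cohorts give chance-level combination scores", {
  scores <- c()
  for (s in 1:3) {
    co <- generate_cohort(default_config(n_per_cell = 15,
                                         group_effect_log2 = 0,
                                         stage_effect_log2 = 0),
                          seed = 600 + s)
    rel <- to_relative(co$table)
    sel <- select_training_combination(
      rel, co$metadata,
      combinations = list(c("normal", "cancer")))
    scores <- c(scores, sel$ranking$score)
  }
  expect_true(all(abs(scores - 0.5) <= 0.15))
})

test_that("adjusted_rand_index behaves on known partitions", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  set.seed(1)
  a <- sample(3, 60, TRUE); b <- sample(3, 60, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.25)
})
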