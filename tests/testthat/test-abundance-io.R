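test_that("genus_table enforces its invariants", {
  m <- matrix(1:4, 2, 2,
              dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_s3_class(genus_table(m, "counts"), "genus_table")
  expect_error(genus_table(unname(m), "counts"), "rownames")
  m_neg <- m; m_neg[1, 1] <- -1
  expect_error(genus_table(m_neg, "counts"), "negative")
  m_dup <- m; rownames(m_dup) <- c("a", "a")
  expect_error(genus_table(m_dup, "counts"), "duplicate sample")
  expect_error(genus_table(m / 2, "relative"), "sum to 1")
})

test_that("TSV round trip preserves values exactly and infers kind", {
  tab <- random_counts(n = 6, p = 9, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path, "tsv")
  back <- read_abundance_table(path, "tsv")
  expect_identical(table_kind(back), "counts")
  expect_identical(unclass(back), unclass(tab))

  rel <- to_relative(tab)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(rel, path2, "tsv")
  back2 <- read_abundance_table(path2, "tsv")
  expect_identical(table_kind(back2), "relative")
  expect_equal(unclass(back2), unclass(rel), tolerance = 1e-12)
})

test_that("malformed TSV inputs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgA\tgB", "s1\t2\t-1", "s2\t1\t4"), path)
  expect_error(read_abundance_table(path, "tsv"), "negative")
  writeLines(c("sample_id\tgA\tgB", "s1\t2\tx", "s2\t1\t4"), path)
  expect_error(read_abundance_table(path, "tsv"), "non-numeric")
  expect_error(read_abundance_table("no/such/file.tsv", "tsv"), "not found")
})

test_that("BIOM round trip preserves values", {
  skip_if_not_installed("biomformat")
  tab <- random_counts(n = 5, p = 7, seed = 11)
  path <- withr::local_tempfile(fileext = ".biom")
  write_abundance_table(tab, path, "biom")
  back <- read_abundance_table(path, "biom")
  expect_equal(unclass(back)[rownames(tab), colnames(tab)],
               unclass(tab), ignore_attr = TRUE)
})

test_that("merge_to_genus sums OTUs per genus and conserves totals", {
  otus <- matrix(c(3, 4, 5,
                   1, 2, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"),
                                 c("OTU1", "OTU2", "OTU3")))
  tax <- c(OTU1 = "A", OTU2 = "A", OTU3 = "B")
  merged <- merge_to_genus(otus, tax)
  expect_equal(unclass(merged)[, "A"], c(s1 = 7, s2 = 3))
  expect_equal(unclass(merged)[, "B"], c(s1 = 5, s2 = 0))

  # identity case: distinct genera leave the table unchanged
  tax_id <- c(OTU1 = "x", OTU2 = "y", OTU3 = "z")
  ident <- merge_to_genus(otus, tax_id)
  expect_equal(unname(unclass(ident)), unname(otus), ignore_attr = TRUE)

  # unassigned OTUs are bucketed, never dropped
  part <- merge_to_genus(otus, c(OTU1 = "A"))
  expect_true("unclassified" %in% colnames(part))
  expect_equal(rowSums(part), rowSums(otus))
  expect_error(merge_to_genus(otus, character(0)), "empty taxonomy")
})

test_that("merge conserves per-sample totals on random OTU tables", {
  for (seed in 1:5) {
    set.seed(seed)
    otus <- matrix(rpois(10 * 20, 8), 10, 20,
                   dimnames = list(sprintf("s%d", 1:10),
                                   sprintf("OTU%d", 1:20)))
    tax <- setNames(sample(paste0("genus", 1:6), 20, replace = TRUE),
                    colnames(otus))
    merged <- merge_to_genus(otus, tax)
    expect_identical(unname(rowSums(merged)), unname(rowSums(otus)))
  }
})

test_that("to_relative normalises rows and is idempotent", {
  rel <- to_relative(tiny_counts())
  expect_equal(unclass(rel)["s1", ], c(gA = 0.2, gB = 0.3, gC = 0.5))
  expect_identical(table_kind(rel), "relative")
  for (seed in 1:5) {
    rel <- to_relative(random_counts(seed = seed))
    expect_true(all(abs(rowSums(rel) - 1) <= 1e-9))
    expect_equal(unclass(to_relative(rel)), unclass(rel))
  }
  zero <- matrix(c(1, 2, 0, 0), 2, 2, byrow = TRUE,
                 dimnames = list(c("ok", "bad"), c("g1", "g2")))
  expect_error(to_relative(genus_table(zero, "counts")), "bad")
})

test_that("prevalence counts detection fractions and is monotone", {
  tab <- genus_table(matrix(c(1, 0, 2, 0, 3, 0, 7, 0, 4, 5,
                              0, 0, 0, 0, 0, 0, 0, 0, 1, 1),
                            ncol = 2,
                            dimnames = list(sprintf("s%d", 1:10),
                                            c("gA", "gB"))), "counts")
  expect_equal(unname(prevalence(tab)["gA"]), 0.6)
  expect_equal(unname(prevalence(tab, sprintf("s%d", 1:5))["gB"]), 0)
  expect_error(prevalence(tab, character(0)), "empty")
  expect_error(prevalence(tab, "nope"), "unknown sample")

  # brute-force recount + monotonicity under subset growth
  rt <- random_counts(n = 12, p = 8, seed = 4)
  full <- prevalence(rt)
  expect_equal(unname(full), unname(colSums(unclass(rt) > 0) / nrow(rt)))
  sub <- rownames(rt)[1:6]
  for (g in colnames(rt)) {
    extra <- setdiff(rownames(rt)[unclass(rt)[, g] > 0], sub)[1]
    if (is.na(extra)) next
    expect_gte(prevalence(rt, c(sub, extra))[g], prevalence(rt, sub)[g])
  }
})

test_that("log2_transform applies the stated zero policies", {
  expect_equal(log2_transform(c(8, 1)), c(3, 0))
  expect_equal(log2_transform(c(0, 0.5, 2)), c(-2, -1, 1))
  expect_equal(log2_transform(c(0, 0.5, 2), "drop"), c(-1, 1))
  expect_error(log2_transform(c(0, 0)), "positive minimum")
  expect_error(log2_transform(c(-1, 2)), "negative")
})

test_that("stage6 to group3 mapping is total and metadata validates", {
  expect_identical(stage6_to_group3(stage6_levels()),
                   c("normal", "adenoma", "adenoma",
                     "cancer", "cancer", "cancer"))
  expect_error(stage6_to_group3("weird"), "unknown stage6")
  md <- cycling_metadata(sprintf("s%d", 1:6))
  expect_identical(md$group3,
                   stage6_to_group3(md$stage6))
  expect_error(cohort_metadata(data.frame(sample_id = c("a", "a"),
                                          stage6 = "normal")),
               "duplicate")
})
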