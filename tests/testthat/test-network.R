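test_that("pearson_network thresholds edges and handles constants", {
  # relative table built directly so that g4 is constant after closure:
  # g1 and g2 duplicated, g3 the complement, g4 fixed at 0.2
  x <- c(0.1, 0.3, 0.15, 0.25, 0.2, 0.12)
  m <- cbind(g1 = x, g2 = x, g3 = 0.8 - 2 * x, g4 = rep(0.2, 6))
  rownames(m) <- sprintf("s%d", 1:6)
  tab <- genus_table(m, "relative")
  # duplicated genus pair -> r = 1 edge; constant genus excluded
  expect_warning(net <- pearson_network(tab, genus_subset = colnames(m)),
                 "g4")
  pair <- net$edges[net$edges$genus_a == "g1" & net$edges$genus_b == "g2", ]
  expect_equal(pair$r, 1, tolerance = 1e-9)
  expect_false("g4" %in% net$nodes)
  # threshold 0 -> complete graph on non-constant genera
  expect_warning(full <- pearson_network(tab, genus_subset = colnames(m),
                                         edge_threshold = 0))
  expect_equal(nrow(full$edges), choose(3, 2))
  # no self edges, each unordered pair at most once
  expect_false(any(full$edges$genus_a == full$edges$genus_b))
  keys <- apply(full$edges[, 1:2], 1, function(v) paste(sort(v), collapse = "|"))
  expect_false(anyDuplicated(keys) > 0)
  expect_error(pearson_network(tab, sample_subset = rownames(m)[1:2]),
               "3 samples")
})

test_that("independent genera produce empty networks at |r| >= 0.5", {
  empty <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    m <- matrix(rgamma(100 * 8, 2), 100, 8,
                dimnames = list(sprintf("s%03d", 1:100),
                                sprintf("g%d", 1:8)))
    tab <- genus_table(m / rowSums(m), "relative")
    net <- pearson_network(tab)
    if (nrow(net$edges) == 0) empty <- empty + 1
  }
  expect_gte(empty, 9)
})

test_that("write_network emits GraphML and edge TSV", {
  tab <- to_relative(random_counts(n = 10, p = 6, seed = 2))
  net <- pearson_network(tab, edge_threshold = 0, group = "normal")
  g_path <- withr::local_tempfile(fileext = ".graphml")
  t_path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, g_path, t_path)
  g <- igraph::read_graph(g_path, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  back <- read.delim(t_path)
  expect_identical(nrow(back), nrow(net$edges))
  expect_true(all(back$group == "normal"))
})

make_partition <- function(cluster_list) {
  df <- data.frame(genus = unlist(cluster_list, use.names = FALSE),
                   cag = rep(seq_along(cluster_list),
                             lengths(cluster_list)))
  structure(df, K = length(cluster_list),
            class = c("cag_partition", "data.frame"))
}

test_that("find_stable_cag returns the largest shared cluster", {
  anchor <- sprintf("a%02d", 1:10)
  p1 <- make_partition(list(anchor, c("x1", "x2"), c("y1", "y2", "y3")))
  p2 <- make_partition(list(c("x1", "y1"), anchor, c("x2", "y2", "y3")))
  p3 <- make_partition(list(c("y3", "x1"), c("x2", "y1", "y2"), anchor))
  expect_identical(find_stable_cag(list(p1, p2, p3)), sort(anchor))
  # order-invariant in the partition list
  expect_identical(find_stable_cag(list(p3, p1, p2)), sort(anchor))
  # identical partitions -> their largest cluster
  expect_identical(find_stable_cag(list(p1, p1)), sort(anchor))
  # no shared cluster -> empty set
  q1 <- make_partition(list(c("a", "b"), c("c", "d")))
  q2 <- make_partition(list(c("a", "c"), c("b", "d")))
  expect_length(find_stable_cag(list(q1, q2)), 0)
  # disjoint universes -> error
  r1 <- make_partition(list(c("a", "b")))
  r2 <- make_partition(list(c("z1", "z2")))
  expect_error(find_stable_cag(list(r1, r2)), "no genera")
})

test_that("relaxed stability accepts near-identical clusters", {
  big <- sprintf("a%02d", 1:9)
  p1 <- make_partition(list(c(big, "extra"), c("x1", "x2")))
  p2 <- make_partition(list(big, c("x1", "x2", "extra")))
  expect_length(find_stable_cag(list(p1, p2)), 0)
  expect_identical(find_stable_cag(list(p1, p2), relaxed = TRUE),
                   sort(c(big, "extra")))
})

test_that("anchor correlation profiles recover planted group switching", {
  # genus tracks the anchor factor in normal samples, independent in
  # cancer samples; a large near-constant filler keeps closure benign
  set.seed(9)
  n <- 100
  anchor_factor_n <- rnorm(n); anchor_factor_c <- rnorm(n)
  anchor <- sprintf("anch%d", 1:5)
  mk <- function(f) 10 + f + rnorm(n, 0, 0.75)
  m_n <- sapply(anchor, function(a) mk(anchor_factor_n))
  m_c <- sapply(anchor, function(a) mk(anchor_factor_c))
  switcher_n <- 10 + 1.2 * anchor_factor_n + rnorm(n, 0, 0.5)
  switcher_c <- 10 + rnorm(n, 0, 1.2)
  indep_n <- 10 + rnorm(n); indep_c <- 10 + rnorm(n)
  base_n <- 200 + matrix(rnorm(n), n, 1)
  base_c <- 200 + matrix(rnorm(n), n, 1)
  m <- rbind(cbind(m_n, Switcher = switcher_n, Indep = indep_n, base_n),
             cbind(m_c, Switcher = switcher_c, Indep = indep_c, base_c))
  colnames(m) <- c(anchor, "Switcher", "Indep", "filler")
  rownames(m) <- sprintf("s%03d", seq_len(2 * n))
  tab <- genus_table(m / rowSums(m), "relative")
  md <- cohort_metadata(data.frame(
    sample_id = rownames(m),
    stage6 = rep(c("normal", "crc_early"), each = n)))
  prof_sw <- anchor_correlation_profile(tab, md, anchor, "Switcher")
  prof_in <- anchor_correlation_profile(tab, md, anchor, "Indep")
  expect_gt(prof_sw["normal"], 0.5)
  expect_lt(abs(prof_sw["cancer"]), 0.25)
  expect_lt(abs(prof_in["normal"]), 0.25)
  expect_lt(abs(prof_in["cancer"]), 0.25)
  profiles <- rbind(Switcher = prof_sw[c("normal", "cancer")],
                    Indep = prof_in[c("normal", "cancer")])
  flags <- variable_genera(profiles)
  expect_true(flags$flagged[flags$genus == "Switcher"])
  expect_false(flags$flagged[flags$genus == "Indep"])
  expect_error(anchor_correlation_profile(tab, md, anchor, anchor[1]),
               "must not belong")
})

test_that("anchor profiles are invariant to affine rescaling of the genus", {
  tab <- to_relative(random_counts(n = 30, p = 8, seed = 12))
  md <- split_metadata(rownames(tab))
  anchor <- colnames(tab)[1:3]
  g <- colnames(tab)[5]
  base <- anchor_correlation_profile(tab, md, anchor, g)
  shifted <- stats::setNames(vapply(c("normal", "cancer"), function(grp) {
    ids <- md$sample_id[md$group3 == grp]
    mean(vapply(anchor, function(a)
      cor(4 * unclass(tab)[ids, g] + 0.01, unclass(tab)[ids, a]), 0))
  }, 0), c("normal", "cancer"))
  expect_equal(unname(base[c("normal", "cancer")]), unname(shifted),
               tolerance = 1e-9)
})

test_that("variable_genera applies its threshold rule", {
  profiles <- rbind(hi = c(0.8, 0.5, 0.0),
                    lo = c(0.5, 0.45, 0.55),
                    part_na = c(NA, 0.2, 0.7))
  out <- variable_genera(profiles)
  expect_true(out$flagged[out$genus == "hi"])
  expect_false(out$flagged[out$genus == "lo"])
  expect_true(out$flagged[out$genus == "part_na"])   # range 0.5 from 2 values
  expect_identical(out$genus[1], "hi")               # sorted by score
  empty <- variable_genera(profiles[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
})
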