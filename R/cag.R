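#' The enterotype-defining driver genera
#'
#' Bacteroides, Prevotella and Escherichia. By default these are
#' excluded from co-abundance clustering: the dominant driver is the
#' bulk of the compositional denominator, so its relative abundance
#' anti-correlates with every other genus purely through closure, which
#' turns cluster-count selection into a driver-versus-rest split rather
#' than a co-abundance structure search (see the methods vignette).
#'
#' @return character vector of the three genus names.
#' @export
enterotype_drivers <- function() c("Bacteroides", "Prevotella", "Escherichia")

#' Genus-genus correlation matrix
#'
#' Spearman (default) or Pearson correlation between genera over a sample
#' subset. Constant genera have no defined correlation and raise an error
#' naming them; callers normally pre-filter with
#' [filter_by_prevalence()].
#'
#' @param table relative [genus_table()].
#' @param sample_subset sample ids (default all); needs >= 3.
#' @param genus_subset genus names (default all); needs >= 2.
#' @param method `"spearman"` or `"pearson"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(table, sample_subset = rownames(table),
                               genus_subset = colnames(table),
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "genus_table"))
  if (length(sample_subset) < 3) stop("need at least 3 samples")
  if (length(genus_subset) < 2) stop("need at least 2 genera")
  m <- unclass(table)[sample_subset, genus_subset, drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant genus (no defined correlation): ",
         paste(genus_subset[sds == 0], collapse = ", "))
  r <- stats::cor(m, method = method)
  attr(r, "method") <- method
  r
}

#' Define co-abundance groups by hierarchical clustering
#'
#' Agglomerative clustering of genera on the distance `d = 1 - r` derived
#' from a correlation matrix. The tree is cut either at a fixed `k` or at
#' the `k` (scanned over `k_range`, default 2..12) maximising the mean
#' silhouette width. When all pairwise correlations are equal the
#' silhouette is uninformative; `k = 2` is returned with a warning.
#'
#' @param corr correlation matrix from [correlation_matrix()].
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param k fixed number of clusters, or `NULL` for the silhouette scan.
#' @param k_range candidate cluster counts for the scan.
#' @param source_groups optional record of which disease groups' samples
#'   built `corr`.
#' @return a `cag_partition`: data.frame (`genus`, `cag`) with attributes
#'   `K`, `linkage`, `method`, `silhouette` (scan profile, if run) and
#'   `source_groups`.
#' @export
define_cags <- function(corr, linkage = "average", k = NULL,
                        k_range = 2:12, source_groups = NULL) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  g <- colnames(corr)
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = linkage)
  sil_profile <- NULL
  if (is.null(k)) {
    k_range <- k_range[k_range >= 2 & k_range < length(g)]
    if (!length(k_range)) stop("no admissible k in k_range")
    sil_profile <- vapply(k_range, function(kk)
      mean_silhouette(as.matrix(d), stats::cutree(hc, k = kk)), 0)
    names(sil_profile) <- k_range
    if (max(sil_profile) <= 0 || diff(range(corr[lower.tri(corr)])) < 1e-12) {
      warning("degenerate correlation structure; defaulting to k = 2")
      k <- 2
    } else {
      k <- k_range[which.max(sil_profile)]
    }
  }
  if (k > length(g)) stop("k exceeds the number of genera")
  cl <- stats::cutree(hc, k = k)
  # contiguous ids 1..K in order of first appearance (cutree guarantees
  # this for its own labels, but keep it explicit)
  cl <- as.integer(factor(cl, levels = unique(cl)))
  out <- data.frame(genus = g, cag = cl, stringsAsFactors = FALSE)
  attr(out, "K") <- max(cl)
  attr(out, "linkage") <- linkage
  attr(out, "method") <- attr(corr, "method")
  attr(out, "silhouette") <- sil_profile
  attr(out, "source_groups") <- source_groups
  class(out) <- c("cag_partition", "data.frame")
  out
}

# mean silhouette width of a labelling over a full distance matrix
mean_silhouette <- function(dmat, labels) {
  n <- nrow(dmat)
  ks <- unique(labels)
  if (length(ks) < 2) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(dmat[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != labels[i]], function(k)
      mean(dmat[i, labels == k]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Per-sample co-abundance group abundances
#'
#' Sums, within each sample, the relative abundances of every CAG's
#' member genera. Mass is conserved exactly: the CAG totals of a sample
#' equal the summed relative abundance of all clustered genera.
#'
#' @param table relative [genus_table()] containing every partition
#'   genus.
#' @param partition a `cag_partition` from [define_cags()].
#' @return samples x K matrix with columns `CAG1..CAGK`.
#' @export
cag_abundance <- function(table, partition) {
  stopifnot(inherits(table, "genus_table"),
            inherits(partition, "cag_partition"))
  missing <- setdiff(partition$genus, colnames(table))
  if (length(missing))
    stop("partition genus/genera missing from table: ",
         paste(missing, collapse = ", "))
  K <- attr(partition, "K")
  prof <- sapply(seq_len(K), function(k)
    rowSums(unclass(table)[, partition$genus[partition$cag == k],
                           drop = FALSE]))
  prof <- matrix(prof, nrow = nrow(table),
                 dimnames = list(rownames(table), paste0("CAG", seq_len(K))))
  prof
}

#' Compare CAG abundances between disease groups
#'
#' Mann-Whitney tests of each CAG's summed abundance for every group
#' pair, overall or within an enterotype stratum -- the CAG-level
#' analogue of [differential_genera()].
#'
#' @param profiles samples x CAG matrix from [cag_abundance()].
#' @param metadata [cohort_metadata()].
#' @param comparisons list of group3 pairs (default all three).
#' @param stratum,enterotypes optional enterotype restriction.
#' @param alpha significance threshold.
#' @return data.frame keyed by CAG with the same columns as a
#'   `differential_result` (prevalence column omitted).
#' @export
compare_cag_abundance <- function(profiles, metadata,
                                  comparisons = list(
                                    c("normal", "adenoma"),
                                    c("normal", "cancer"),
                                    c("adenoma", "cancer")),
                                  stratum = NULL, enterotypes = NULL,
                                  alpha = 0.01) {
  ids <- rownames(profiles)
  if (!is.null(stratum)) {
    if (is.null(enterotypes))
      stop("stratified testing needs the enterotype labels")
    ids <- intersect(ids, enterotypes$sample_id[
      enterotypes$enterotype == stratum])
  }
  g <- metadata$group3[match(ids, metadata$sample_id)]
  rows <- list()
  for (cmp in comparisons) {
    ia <- ids[g == cmp[1]]; ib <- ids[g == cmp[2]]
    if (length(ia) < 2 || length(ib) < 2) {
      warning("skipping ", cmp[1], " vs ", cmp[2],
              " (fewer than 2 samples in a group)")
      next
    }
    for (cag in colnames(profiles)) {
      x <- profiles[ia, cag]; y <- profiles[ib, cag]
      mw <- suppressMessages(mann_whitney_two_sided(x, y))
      dmed <- stats::median(y) - stats::median(x)
      rows[[length(rows) + 1]] <- data.frame(
        cag = cag, group_a = cmp[1], group_b = cmp[2],
        stratum = if (is.null(stratum)) "all" else stratum,
        n_a = length(ia), n_b = length(ib),
        u_statistic = mw$U, p_value = mw$p,
        direction = if (dmed > 0) "up_in_second"
        else if (dmed < 0) "down_in_second" else "none",
        significant = mw$p < alpha, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cag = character(), group_a = character(),
                      group_b = character(), stratum = character(),
                      n_a = integer(), n_b = integer(),
                      u_statistic = numeric(), p_value = numeric(),
                      direction = character(), significant = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$p_value), ]
}

#' Choose the sample combination that builds the most discriminative CAGs
#'
#' For each candidate combination of disease groups (e.g. normal+cancer),
#' CAGs are clustered from that combination's samples only; CAG abundance
#' profiles are then computed for all samples, and the combination is
#' scored by leave-one-out nearest-centroid accuracy at separating the
#' target pair (default adenoma vs cancer) in CAG-abundance space.
#' Ties are broken towards fewer source groups, then lexicographically.
#'
#' @param table relative [genus_table()].
#' @param metadata [cohort_metadata()].
#' @param combinations list of character vectors of group3 labels;
#'   default all 7 non-empty subsets of normal/adenoma/cancer.
#' @param target_pair the two groups to classify.
#' @param method,linkage,k,k_range forwarded to [correlation_matrix()]
#'   and [define_cags()].
#' @param prevalence_filter apply the cancer-prevalence filter before
#'   correlation (default TRUE).
#' @param exclude_genera genera dropped before clustering (default the
#'   [enterotype_drivers()]; pass `character(0)` to keep them).
#' @return list with `ranking` (data.frame combination/score, descending)
#'   and `winner` (the winning `cag_partition`).
#' @export
select_training_combination <- function(table, metadata,
                                        combinations = list(
                                          "normal", "adenoma", "cancer",
                                          c("normal", "adenoma"),
                                          c("normal", "cancer"),
                                          c("adenoma", "cancer"),
                                          c("normal", "adenoma", "cancer")),
                                        target_pair = c("adenoma", "cancer"),
                                        method = "spearman",
                                        linkage = "average",
                                        k = NULL, k_range = 2:12,
                                        prevalence_filter = TRUE,
                                        exclude_genera = enterotype_drivers()) {
  if (!length(combinations)) stop("empty combination list")
  genera <- colnames(table)
  if (prevalence_filter)
    genera <- filter_by_prevalence(table, metadata, "cancer")
  genera <- setdiff(genera, exclude_genera)
  g3 <- metadata$group3[match(rownames(table), metadata$sample_id)]
  target_ids <- rownames(table)[g3 %in% target_pair]
  target_lab <- g3[g3 %in% target_pair]
  scores <- numeric(length(combinations))
  partitions <- vector("list", length(combinations))
  labels <- vapply(combinations, function(cmb)
    paste(sort(cmb), collapse = "+"), "")
  for (ci in seq_along(combinations)) {
    cmb <- combinations[[ci]]
    if (!length(cmb)) stop("empty combination")
    ids <- rownames(table)[g3 %in% cmb]
    # drop genera constant within the training samples
    sds <- apply(unclass(table)[ids, genera, drop = FALSE], 2, stats::sd)
    gg <- genera[sds > 0]
    corr <- correlation_matrix(table, ids, gg, method = method)
    part <- define_cags(corr, linkage = linkage, k = k, k_range = k_range,
                        source_groups = cmb)
    partitions[[ci]] <- part
    prof <- cag_abundance(table, part)[target_ids, , drop = FALSE]
    scores[ci] <- loo_nearest_centroid(prof, target_lab)
  }
  ord <- order(-scores, lengths(combinations), labels)
  ranking <- data.frame(combination = labels[ord],
                        n_source_groups = lengths(combinations)[ord],
                        score = scores[ord], stringsAsFactors = FALSE)
  list(ranking = ranking, winner = partitions[[ord[1]]])
}

# leave-one-out nearest-centroid accuracy for a two-class labelling
loo_nearest_centroid <- function(x, labels) {
  labs <- unique(labels)
  stopifnot(length(labs) == 2)
  correct <- 0
  sums <- rbind(colSums(x[labels == labs[1], , drop = FALSE]),
                colSums(x[labels == labs[2], , drop = FALSE]))
  ns <- c(sum(labels == labs[1]), sum(labels == labs[2]))
  for (i in seq_len(nrow(x))) {
    li <- match(labels[i], labs)
    cent <- sums
    n <- ns
    cent[li, ] <- cent[li, ] - x[i, ]
    n[li] <- n[li] - 1
    if (any(n == 0)) next
    d1 <- sum((x[i, ] - cent[1, ] / n[1])^2)
    d2 <- sum((x[i, ] - cent[2, ] / n[2])^2)
    pred <- if (d1 <= d2) labs[1] else labs[2]
    if (pred == labels[i]) correct <- correct + 1
  }
  correct / nrow(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items;
#' 1 for identical partitions (up to relabelling), ~0 for independent
#' ones. Used to score recovery of planted co-abundance blocks.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
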