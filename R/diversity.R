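#' Genus richness of one sample
#'
#' Number of genera detected (strictly positive abundance). Works
#' identically on counts and relative abundances.
#'
#' @param sample non-negative numeric vector with at least one positive
#'   entry.
#' @return integer count.
#' @export
richness <- function(sample) {
  if (any(sample < 0)) stop("negative abundance")
  if (!any(sample > 0)) stop("all-zero sample")
  sum(sample > 0)
}

#' Shannon diversity of one sample (nats)
#'
#' `H = -sum(p_i * ln(p_i))` over the positive entries after normalising
#' the vector to proportions. Invariant to positive rescaling; 0 when a
#' single genus is present; at most `ln(richness)`.
#'
#' @inheritParams richness
#' @return non-negative numeric.
#' @export
shannon <- function(sample) {
  if (any(sample < 0)) stop("negative abundance")
  if (!any(sample > 0)) stop("all-zero sample")
  p <- sample[sample > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Per-sample alpha diversity of a cohort
#'
#' Computes genus richness, Shannon index (nats) and the binary logarithm
#' of richness for every sample. Richness is taken from the count table
#' when one is supplied (a genus counts as present when any read mapped to
#' it), otherwise from the positive entries of `table` itself.
#'
#' @param table a [genus_table()] (counts or relative).
#' @param counts_table optional counts [genus_table()] over the same
#'   samples, used for the detection calls.
#' @return data.frame `sample_id`, `richness`, `shannon`,
#'   `log2_richness`.
#' @export
alpha_diversity <- function(table, counts_table = NULL) {
  stopifnot(inherits(table, "genus_table"))
  det <- if (is.null(counts_table)) table else counts_table
  data.frame(
    sample_id = rownames(table),
    richness = apply(unclass(det), 1, richness),
    shannon = apply(unclass(table), 1, shannon),
    log2_richness = log2(apply(unclass(det), 1, richness)),
    stringsAsFactors = FALSE)
}

#' Compare alpha diversity between disease groups
#'
#' Two-sided Mann-Whitney rank tests of a diversity metric for every pair
#' of disease groups, optionally restricted to one enterotype stratum.
#' Pairs in which either group has fewer than 2 samples are skipped with
#' a warning.
#'
#' @param div result of [alpha_diversity()].
#' @param metadata a [cohort_metadata()].
#' @param metric `"richness"` or `"shannon"`.
#' @param stratum optional enterotype label (`"I"`, `"II"`, `"III"`)
#'   requiring `enterotypes`.
#' @param enterotypes result of [enterotype_cohort()] (needed when
#'   `stratum` is set).
#' @param alpha significance threshold (default 0.01, two-sided).
#' @return data.frame, one row per group pair: medians, U, p,
#'   `significant`.
#' @export
compare_diversity <- function(div, metadata,
                              metric = c("richness", "shannon"),
                              stratum = NULL, enterotypes = NULL,
                              alpha = 0.01) {
  metric <- match.arg(metric)
  ids <- div$sample_id
  if (!is.null(stratum)) {
    if (is.null(enterotypes))
      stop("stratified comparison needs the enterotype labels")
    keep <- enterotypes$sample_id[enterotypes$enterotype == stratum]
    ids <- intersect(ids, keep)
  }
  g <- metadata$group3[match(ids, metadata$sample_id)]
  v <- div[[metric]][match(ids, div$sample_id)]
  groups <- intersect(group3_levels(), unique(g))
  out <- list()
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (a >= b) next
    x <- v[g == groups[a]]
    y <- v[g == groups[b]]
    if (length(x) < 2 || length(y) < 2) {
      warning("skipping ", groups[a], " vs ", groups[b],
              " (fewer than 2 samples in a group)")
      next
    }
    mw <- mann_whitney_two_sided(x, y)
    out[[length(out) + 1]] <- data.frame(
      group_a = groups[a], group_b = groups[b],
      stratum = if (is.null(stratum)) "all" else stratum,
      metric = metric, n_a = length(x), n_b = length(y),
      median_a = stats::median(x), median_b = stats::median(y),
      u_statistic = mw$U, p_value = mw$p,
      significant = mw$p < alpha, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(group_a = character(), group_b = character(),
                      stratum = character(), metric = character(),
                      n_a = integer(), n_b = integer(),
                      median_a = numeric(), median_b = numeric(),
                      u_statistic = numeric(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
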