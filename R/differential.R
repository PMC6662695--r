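#' Filter genera by prevalence in a reference group
#'
#' Keeps the genera detected in strictly more than `threshold` of the
#' reference group's samples (default: present in more than 50 % of the
#' cancer group), preserving the table's column order. This filter
#' precedes both differential testing and co-abundance clustering.
#'
#' @param table a [genus_table()].
#' @param metadata a [cohort_metadata()].
#' @param reference_group group3 label (default `"cancer"`).
#' @param threshold prevalence cut-off; strict inequality.
#' @return character vector of genus names.
#' @export
filter_by_prevalence <- function(table, metadata,
                                 reference_group = "cancer",
                                 threshold = 0.5) {
  if (!reference_group %in% group3_levels())
    stop("unknown group label: ", reference_group)
  ids <- intersect(samples_of_group(metadata, reference_group),
                   rownames(table))
  if (!length(ids)) stop("reference group has no samples in the table")
  prev <- prevalence(table, ids)
  colnames(table)[prev > threshold]
}

#' Rank-based differential abundance between disease groups
#'
#' For every genus passing the cancer-prevalence filter and every
#' requested pair of disease groups, runs the two-sided Mann-Whitney test
#' on relative abundances, overall or within one enterotype stratum.
#' Direction is read from the group medians (`up_in_second` means the
#' second group of the pair has the higher median). Results are sorted by
#' p-value. Optional Benjamini-Hochberg adjustment is off by default,
#' matching the raw p < 0.01 convention of the analysis this package
#' implements.
#'
#' @param table relative [genus_table()].
#' @param metadata [cohort_metadata()].
#' @param comparisons list of 2-vectors of group3 labels; default all
#'   three pairs.
#' @param stratum optional enterotype label; requires `enterotypes`.
#' @param enterotypes result of [enterotype_cohort()].
#' @param alpha significance threshold on the (possibly adjusted) p.
#' @param prevalence_filter apply the >50 % cancer-prevalence filter
#'   first (default TRUE).
#' @param reference_group prevalence-filter reference group.
#' @param bh apply Benjamini-Hochberg adjustment before flagging.
#' @return data.frame of class `differential_result`: genus, comparison,
#'   stratum, n per group, U, p (and `p_adjusted` if `bh`), prevalence in
#'   the reference group, direction, significant.
#' @export
differential_genera <- function(table, metadata,
                                comparisons = list(
                                  c("normal", "adenoma"),
                                  c("normal", "cancer"),
                                  c("adenoma", "cancer")),
                                stratum = NULL, enterotypes = NULL,
                                alpha = 0.01, prevalence_filter = TRUE,
                                reference_group = "cancer", bh = FALSE) {
  stopifnot(inherits(table, "genus_table"))
  if (!identical(table_kind(table), "relative"))
    stop("differential testing expects a relative table")
  empty <- data.frame(genus = character(), group_a = character(),
                      group_b = character(), stratum = character(),
                      n_a = integer(), n_b = integer(),
                      u_statistic = numeric(), p_value = numeric(),
                      prevalence_in_reference = numeric(),
                      direction = character(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (!length(comparisons)) return(empty)
  genera <- colnames(table)
  ref_ids <- intersect(samples_of_group(metadata, reference_group),
                       rownames(table))
  prev <- prevalence(table, ref_ids)
  if (prevalence_filter)
    genera <- filter_by_prevalence(table, metadata, reference_group)
  ids <- rownames(table)
  if (!is.null(stratum)) {
    if (is.null(enterotypes))
      stop("stratified testing needs the enterotype labels")
    ids <- intersect(ids, enterotypes$sample_id[
      enterotypes$enterotype == stratum])
  }
  g <- metadata$group3[match(ids, metadata$sample_id)]
  rows <- list()
  for (cmp in comparisons) {
    ia <- ids[g == cmp[1]]
    ib <- ids[g == cmp[2]]
    if (length(ia) < 2 || length(ib) < 2) {
      warning("skipping ", cmp[1], " vs ", cmp[2],
              if (is.null(stratum)) "" else paste0(" in enterotype ", stratum),
              " (fewer than 2 samples in a group)")
      next
    }
    for (gen in genera) {
      x <- unclass(table)[ia, gen]
      y <- unclass(table)[ib, gen]
      mw <- suppressMessages(mann_whitney_two_sided(x, y))
      dmed <- stats::median(y) - stats::median(x)
      rows[[length(rows) + 1]] <- data.frame(
        genus = gen, group_a = cmp[1], group_b = cmp[2],
        stratum = if (is.null(stratum)) "all" else stratum,
        n_a = length(ia), n_b = length(ib),
        u_statistic = mw$U, p_value = mw$p,
        prevalence_in_reference = unname(prev[gen]),
        direction = if (dmed > 0) "up_in_second"
        else if (dmed < 0) "down_in_second" else "none",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  if (bh) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Differential abundance along the stage-transition sequence
#'
#' Tests consecutive pairs of an ordered pathology-stage sequence
#' (default: advanced adenoma -> carcinoma in situ -> early-stage
#' carcinoma), the path along which stage-specific depletions such as
#' Oscillospira (advanced adenoma to stage 0) and Haemophilus (stage 0 to
#' early stage) are expected. The prevalence filter is referenced to the
#' pooled cancer stages.
#'
#' @param table relative [genus_table()].
#' @param metadata [cohort_metadata()].
#' @param ordered_stages character vector of stage6 labels, length >= 2.
#' @param alpha significance threshold.
#' @param prevalence_filter apply the cancer-prevalence filter.
#' @return a `differential_result` data.frame over consecutive stage
#'   pairs (group columns hold stage labels).
#' @export
transition_analysis <- function(table, metadata,
                                ordered_stages = c("advanced_adenoma",
                                                   "crc_stage0",
                                                   "crc_early"),
                                alpha = 0.01, prevalence_filter = TRUE) {
  if (length(ordered_stages) < 2)
    stop("need at least 2 stages for a transition analysis")
  bad <- setdiff(ordered_stages, stage6_levels())
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  genera <- colnames(table)
  ref_ids <- intersect(samples_of_group(metadata, "cancer"),
                       rownames(table))
  prev <- prevalence(table, ref_ids)
  if (prevalence_filter)
    genera <- filter_by_prevalence(table, metadata, "cancer")
  s <- metadata$stage6[match(rownames(table), metadata$sample_id)]
  rows <- list()
  for (i in seq_len(length(ordered_stages) - 1)) {
    st_a <- ordered_stages[i]; st_b <- ordered_stages[i + 1]
    ia <- rownames(table)[s == st_a]
    ib <- rownames(table)[s == st_b]
    if (length(ia) < 2 || length(ib) < 2) {
      warning("skipping ", st_a, " vs ", st_b,
              " (fewer than 2 samples in a stage)")
      next
    }
    for (gen in genera) {
      x <- unclass(table)[ia, gen]
      y <- unclass(table)[ib, gen]
      mw <- suppressMessages(mann_whitney_two_sided(x, y))
      dmed <- stats::median(y) - stats::median(x)
      rows[[length(rows) + 1]] <- data.frame(
        genus = gen, group_a = st_a, group_b = st_b, stratum = "all",
        n_a = length(ia), n_b = length(ib),
        u_statistic = mw$U, p_value = mw$p,
        prevalence_in_reference = unname(prev[gen]),
        direction = if (dmed > 0) "up_in_second"
        else if (dmed < 0) "down_in_second" else "none",
        significant = mw$p < alpha, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no testable consecutive stage pair (need >= 2 samples per stage)")
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}
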