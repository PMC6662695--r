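#' Build a covariate-by-group contingency table
#'
#' Cross-tabulates one categorical covariate against the three disease
#' groups. The literal level `"Unknown"` is a real category and is kept
#' by default -- the convention under which the published cohort table's
#' chi-square p-values reproduce; `include_unknown = FALSE` drops those
#' subjects for sensitivity analysis.
#'
#' @param metadata a [cohort_metadata()].
#' @param variable covariate column name.
#' @param include_unknown keep `"Unknown"` as a level (default TRUE).
#' @return a `contingency_table`: integer matrix (levels x group3) with
#'   attributes `variable` and `include_unknown`.
#' @export
build_contingency <- function(metadata, variable, include_unknown = TRUE) {
  if (!variable %in% names(metadata))
    stop("unknown variable '", variable, "'; available: ",
         paste(setdiff(names(metadata),
                       c("sample_id", "stage6", "group3")), collapse = ", "))
  v <- as.character(metadata[[variable]])
  g <- factor(metadata$group3, levels = group3_levels())
  keep <- !is.na(v) & v != ""
  if (!include_unknown) keep <- keep & v != "Unknown"
  counts <- table(level = v[keep], group3 = g[keep])
  counts <- unclass(counts)[, group3_levels(), drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(counts, variable = variable,
            include_unknown = include_unknown,
            class = c("contingency_table", "matrix"))
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square without continuity correction, with
#' `df = (rows - 1) * (cols - 1)` and the p-value from the chi-square
#' distribution. Errors on zero row/column margins and on degenerate
#' (single-row or single-column) tables.
#'
#' @param ct a `contingency_table` (or plain count matrix).
#' @return list `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(ct) {
  m <- matrix(as.numeric(ct), nrow = nrow(ct))
  if (any(m < 0) || anyNA(m)) stop("counts must be non-negative")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row/column margin; drop empty levels first")
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  if (df < 1) stop("degenerate table (df = 0)")
  expected <- outer(rs, cs) / sum(m)
  statistic <- sum((m - expected)^2 / expected)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Chi-square tests for a set of cohort covariates
#'
#' Convenience wrapper running [build_contingency()] +
#' [chi_square_test()] over several covariates.
#'
#' @param metadata a [cohort_metadata()].
#' @param variables covariate column names.
#' @param include_unknown see [build_contingency()].
#' @return data.frame `variable`, `n_levels`, `chi2`, `df`, `p_value`.
#' @export
cohort_covariate_tests <- function(metadata, variables,
                                   include_unknown = TRUE) {
  rows <- lapply(variables, function(v) {
    ct <- build_contingency(metadata, v, include_unknown)
    res <- chi_square_test(ct)
    data.frame(variable = v, n_levels = nrow(ct),
               chi2 = res$statistic, df = res$df, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
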