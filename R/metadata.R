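#' Cohort metadata
#'
#' Sample-level clinical metadata. Every sample carries a six-level
#' pathology stage (`stage6`) from which the three-level disease group
#' (`group3`) is derived deterministically:
#' small and advanced adenomas collapse to `"adenoma"`, all carcinoma
#' stages (in situ / stage 0, early = I-II, late = III-IV) to `"cancer"`.
#' Additional covariate columns (gender, smoking, comorbidities, ...) are
#' kept as-is; the literal string `"Unknown"` is a real category level,
#' not missing data.
#'
#' @param df data.frame with at least `sample_id` and `stage6` columns.
#' @return the data.frame with a validated `group3` column appended,
#'   classed `cohort_metadata`.
#' @export
cohort_metadata <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("sample_id", "stage6") %in% names(df)))
    stop("metadata requires sample_id and stage6 columns")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  bad <- setdiff(unique(df$stage6), stage6_levels())
  if (length(bad))
    stop("unknown stage6 level(s): ", paste(bad, collapse = ", "))
  df$group3 <- stage6_to_group3(df$stage6)
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' @rdname cohort_metadata
#' @export
stage6_levels <- function() {
  c("normal", "small_adenoma", "advanced_adenoma",
    "crc_stage0", "crc_early", "crc_late")
}

#' @rdname cohort_metadata
#' @export
group3_levels <- function() c("normal", "adenoma", "cancer")

#' Map the six pathology stages onto the three disease groups
#'
#' @param stage6 character vector of stage labels (see [stage6_levels()]).
#' @return character vector over `normal` / `adenoma` / `cancer`.
#' @export
stage6_to_group3 <- function(stage6) {
  map <- c(normal = "normal",
           small_adenoma = "adenoma", advanced_adenoma = "adenoma",
           crc_stage0 = "cancer", crc_early = "cancer", crc_late = "cancer")
  out <- map[as.character(stage6)]
  if (anyNA(out))
    stop("unknown stage6 level(s): ",
         paste(unique(stage6[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Read cohort metadata from TSV
#'
#' One row per sample; columns `sample_id`, `stage6` and any covariates.
#' `"Unknown"` strings are preserved as category levels.
#'
#' @param path TSV file path.
#' @return a [cohort_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = character(0))
  cohort_metadata(df)
}

#' The packaged 283-subject cohort covariate fixture
#'
#' Subject-level metadata reconstructed from published per-stage marginal
#' counts of a 283-subject colonoscopy cohort (104 normal, 117 adenoma,
#' 62 colorectal cancer). Covariates are assigned within each pathology
#' stage to match every variable's printed per-stage counts exactly; the
#' joint distribution across covariates within a stage is otherwise
#' arbitrary (only marginals were published), which leaves every
#' single-covariate contingency table exact. Age and BMI are synthetic
#' per-subject values matching the printed per-stage means and standard
#' deviations approximately.
#'
#' @return a [cohort_metadata()] data.frame with 283 rows.
#' @export
table1_metadata <- function() {
  path <- system.file("extdata", "table1_metadata.tsv",
                      package = "enterocag", mustWork = TRUE)
  read_metadata(path)
}

# resolve the samples of one group3 (or one stage6) label
samples_of_group <- function(metadata, group,
                             column = c("group3", "stage6")) {
  column <- match.arg(column)
  if (!group %in% metadata[[column]])
    stop("no samples with ", column, " = '", group, "'")
  metadata$sample_id[metadata[[column]] == group]
}
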