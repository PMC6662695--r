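# Builds inst/extdata/table1_metadata.tsv: a 283-subject, one-row-per-subject
# reconstruction of the published cohort covariate table. Stages (columns of
# the published table): normal 104, small adenoma 58, advanced adenoma 59,
# carcinoma in situ 21, early-stage 21, late-stage 20. For each covariate the
# published per-stage level counts are assigned within-stage in level order;
# only marginal counts were published, so the within-stage joint distribution
# is arbitrary and every single-covariate contingency table is exact.
#
# One reconciliation: the published per-stage gender splits (15:5 early,
# 11:10 late) sum to 20 and 21, contradicting the printed stage totals
# (21 and 20). One female subject is moved from late to early stage
# (-> 15:6 and 11:9), preserving the per-group margins (M:F = 53:51 normal,
# 80:37 adenoma, 40:22 cancer) used by the chi-square tests.
#
# Age and BMI are synthetic per-subject values: deterministic normal
# quantiles matching each stage's published mean and SD, age clipped to the
# published 40-86 range.

stages <- c("normal", "small_adenoma", "advanced_adenoma",
            "crc_stage0", "crc_early", "crc_late")
n_stage <- c(104, 58, 59, 21, 21, 20)

fill <- function(level_counts) {
  # level_counts: named list level -> per-stage counts (length 6)
  unlist(lapply(seq_along(stages), function(si) {
    rep(names(level_counts),
        vapply(level_counts, function(x) x[si], 0))
  }))
}

covariates <- list(
  gender = list(M = c(53, 40, 40, 14, 15, 11),
                F = c(51, 18, 19, 7, 6, 9)),   # see header note
  hypertension = list(Yes = c(35, 24, 33, 7, 10, 11),
                      No = c(65, 29, 20, 12, 10, 9),
                      Unknown = c(4, 5, 6, 2, 1, 0)),
  hyperlipidemia = list(Yes = c(35, 26, 30, 10, 7, 4),
                        No = c(59, 25, 20, 10, 10, 15),
                        Unknown = c(10, 7, 9, 1, 4, 1)),
  diabetes = list(Yes = c(19, 7, 15, 9, 6, 4),
                  No = c(75, 48, 38, 11, 13, 16),
                  Unknown = c(10, 3, 6, 1, 2, 0)),
  cardiovascular_disease = list(Yes = c(16, 7, 13, 3, 9, 2),
                                No = c(73, 48, 35, 16, 9, 18),
                                Unknown = c(15, 3, 11, 2, 3, 0)),
  family_history_colon_polyp = list(Yes = c(4, 1, 1, 0, 1, 0),
                                    No = c(100, 57, 58, 21, 20, 20)),
  family_history_colorectal_cancer = list(Yes = c(7, 6, 8, 2, 4, 0),
                                          No = c(97, 52, 51, 19, 17, 20)),
  smoking = list(Current_smoker = c(13, 9, 14, 5, 6, 6),
                 Ex_smoker = c(20, 21, 14, 7, 6, 5),
                 Non_smoker = c(71, 28, 31, 9, 9, 9)),
  lesion_site = list(Proximal = c(0, 29, 28, 7, 10, 8),
                     Distal = c(0, 29, 31, 14, 11, 12),
                     Unknown = c(104, 0, 0, 0, 0, 0)))

for (v in names(covariates)) {
  per_stage <- Reduce(`+`, covariates[[v]])
  stopifnot(identical(unname(per_stage), n_stage))
}

age_stats <- list(c(60.71, 10.44), c(60.96, 10.09), c(61.12, 10.10),
                  c(61.00, 10.07), c(61.08, 10.14), c(61.09, 10.27))
bmi_stats <- list(c(23.67, 3.34), c(24.08, 3.42), c(24.12, 3.44),
                  c(24.11, 3.43), c(24.09, 3.43), c(24.01, 3.43))
quantile_values <- function(n, mean, sd)
  qnorm((seq_len(n) - 0.5) / n, mean, sd)

df <- data.frame(
  sample_id = sprintf("SUBJ%03d", seq_len(sum(n_stage))),
  stage6 = rep(stages, n_stage),
  stringsAsFactors = FALSE)
df$age <- round(pmin(86, pmax(40, unlist(mapply(
  function(n, st) quantile_values(n, st[1], st[2]),
  n_stage, age_stats, SIMPLIFY = FALSE)))))
df$bmi <- round(unlist(mapply(
  function(n, st) quantile_values(n, st[1], st[2]),
  n_stage, bmi_stats, SIMPLIFY = FALSE)), 1)
for (v in names(covariates)) df[[v]] <- fill(covariates[[v]])

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(df, "inst/extdata/table1_metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", nrow(df), "subjects\n")
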