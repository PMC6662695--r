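#' Run configuration for the full analysis
#'
#' Declarative description of one end-to-end run: either paths to a
#' genus table + metadata, or a synthetic-cohort specification (exactly
#' one of the two), plus stage toggles and the tunable parameters of
#' every stage. Any parameter omitted takes the documented default.
#'
#' @param table_path,metadata_path input files (TSV), or `NULL` when
#'   simulating.
#' @param synthetic logical; generate the cohort with
#'   [generate_cohort()].
#' @param seed integer seed (synthetic input and any stochastic stage).
#' @param outdir output directory.
#' @param stages character vector of stages to run, a subset of
#'   `c("enterotype", "diversity", "diffabund", "transitions", "cag",
#'   "network", "cohort_stats")`.
#' @param params named list of stage parameter overrides
#'   (`alpha`, `correlation_method`, `linkage`, `k`, `edge_threshold`,
#'   `variability_threshold`, `prevalence_threshold`, `distance`,
#'   `combinations`).
#' @param synthetic_args named list forwarded to [default_config()].
#' @return a validated `run_config` list.
#' @export
run_config <- function(table_path = NULL, metadata_path = NULL,
                       synthetic = is.null(table_path), seed = 1,
                       outdir = "enterocag_run",
                       stages = c("enterotype", "diversity", "diffabund",
                                  "transitions", "cag", "network",
                                  "cohort_stats"),
                       params = list(), synthetic_args = list()) {
  real <- !is.null(table_path) || !is.null(metadata_path)
  if (real && synthetic)
    stop("exactly one of file input and synthetic input must be used")
  if (!real && !synthetic)
    stop("no input: give table_path/metadata_path or synthetic = TRUE")
  if (real && (is.null(table_path) || is.null(metadata_path)))
    stop("file input needs both table_path and metadata_path")
  defaults <- list(alpha = 0.01, correlation_method = "spearman",
                   linkage = "average", k = NULL, edge_threshold = 0.5,
                   variability_threshold = 0.4,
                   prevalence_threshold = 0.5, distance = "bray_curtis",
                   combinations = list("normal", "adenoma", "cancer",
                                       c("normal", "adenoma"),
                                       c("normal", "cancer"),
                                       c("adenoma", "cancer"),
                                       c("normal", "adenoma", "cancer")))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, params)
  structure(list(table_path = table_path, metadata_path = metadata_path,
                 synthetic = synthetic, seed = as.integer(seed),
                 outdir = outdir, stages = stages, params = params,
                 synthetic_args = synthetic_args),
            class = "run_config")
}

#' Execute the full enterotype/CAG analysis
#'
#' Runs the enabled stages in dependency order -- enterotyping,
#' diversity, differential abundance, stage transitions, CAG
#' construction and comparison, anchor network, cohort covariate
#' statistics -- writing each stage's TSV outputs under
#' `config$outdir` together with a machine-readable `run_summary.json`
#' (seed, parameters, per-stage output paths). Re-running with an
#' identical config and seed reproduces the outputs bit-identically.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory stage results and the
#'   summary.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  outputs <- list()
  emit <- function(df, name) {
    path <- file.path(config$outdir, paste0(name, ".tsv"))
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs[[name]] <<- path
  }
  if (config$synthetic) {
    cohort <- do.call(
      generate_cohort,
      list(config = do.call(default_config, config$synthetic_args),
           seed = config$seed))
    counts <- cohort$table
    metadata <- cohort$metadata
    write_cohort(cohort, file.path(config$outdir, "synthetic_input"))
  } else {
    counts <- read_abundance_table(config$table_path, "tsv")
    metadata <- read_metadata(config$metadata_path)
  }
  rel <- to_relative(counts)
  results <- list(metadata = metadata)
  stage_fail <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         "; partial outputs in ", config$outdir, call. = FALSE)
  ets <- NULL
  if ("enterotype" %in% config$stages) {
    tryCatch({
      ets <- enterotype_cohort(rel, metadata)
      emit(ets, "enterotypes")
      ord <- pcoa_ordination(rel, distance = p$distance)
      emit(data.frame(sample_id = rownames(ord$coordinates),
                      ord$coordinates), "ordination")
      results$enterotypes <- ets
      results$ordination <- ord
    }, error = function(e) stage_fail("enterotype", e))
  }
  if ("diversity" %in% config$stages) {
    tryCatch({
      div <- alpha_diversity(rel, counts_table = counts)
      emit(div, "diversity")
      cmp <- compare_diversity(div, metadata, "richness", alpha = p$alpha)
      cmp <- rbind(cmp, compare_diversity(div, metadata, "shannon",
                                          alpha = p$alpha))
      if (!is.null(ets)) {
        for (et in c("I", "II", "III"))
          cmp <- rbind(cmp, suppressWarnings(
            compare_diversity(div, metadata, "richness", stratum = et,
                              enterotypes = ets, alpha = p$alpha)))
      }
      emit(cmp, "diversity_comparisons")
      results$diversity <- div
      results$diversity_comparisons <- cmp
    }, error = function(e) stage_fail("diversity", e))
  }
  if ("diffabund" %in% config$stages) {
    tryCatch({
      da <- differential_genera(rel, metadata, alpha = p$alpha)
      if (!is.null(ets)) {
        for (et in c("I", "II", "III"))
          da <- rbind(da, suppressWarnings(
            differential_genera(rel, metadata, stratum = et,
                                enterotypes = ets, alpha = p$alpha)))
      }
      emit(da, "differential_abundance")
      results$differential <- da
    }, error = function(e) stage_fail("diffabund", e))
  }
  if ("transitions" %in% config$stages) {
    tryCatch({
      tr <- suppressWarnings(
        transition_analysis(rel, metadata, alpha = p$alpha))
      emit(tr, "transitions")
      results$transitions <- tr
    }, error = function(e) stage_fail("transitions", e))
  }
  cag_part <- NULL
  if ("cag" %in% config$stages) {
    tryCatch({
      sel <- select_training_combination(
        rel, metadata, combinations = p$combinations,
        method = p$correlation_method, linkage = p$linkage, k = p$k)
      emit(sel$ranking, "cag_combination_ranking")
      cag_part <- sel$winner
      emit(cag_part, "cag_partition")
      prof <- cag_abundance(rel, cag_part)
      emit(data.frame(sample_id = rownames(prof), prof), "cag_profiles")
      cagcmp <- compare_cag_abundance(prof, metadata, alpha = p$alpha)
      if (!is.null(ets)) {
        for (et in c("I", "II", "III"))
          cagcmp <- rbind(cagcmp, suppressWarnings(
            compare_cag_abundance(prof, metadata, stratum = et,
                                  enterotypes = ets, alpha = p$alpha)))
      }
      emit(cagcmp, "cag_comparisons")
      results$cag <- list(ranking = sel$ranking, partition = cag_part,
                          profiles = prof, comparisons = cagcmp)
    }, error = function(e) stage_fail("cag", e))
  }
  if ("network" %in% config$stages) {
    tryCatch({
      genera <- setdiff(
        filter_by_prevalence(rel, metadata,
                             threshold = p$prevalence_threshold),
        enterotype_drivers())
      g3 <- metadata$group3[match(rownames(rel), metadata$sample_id)]
      partitions <- list()
      edge_rows <- list()
      for (grp in intersect(group3_levels(), unique(g3))) {
        ids <- rownames(rel)[g3 == grp]
        sds <- apply(unclass(rel)[ids, genera, drop = FALSE], 2, stats::sd)
        gg <- genera[sds > 0]
        corr <- correlation_matrix(rel, ids, gg,
                                   method = p$correlation_method)
        partitions[[grp]] <- define_cags(corr, linkage = p$linkage,
                                         source_groups = grp)
        net <- pearson_network(rel, ids, gg,
                               edge_threshold = p$edge_threshold,
                               group = grp)
        if (nrow(net$edges)) {
          e <- net$edges; e$group <- grp
          edge_rows[[grp]] <- e
        }
        write_network(net, graphml_path = file.path(
          config$outdir, paste0("network_", grp, ".graphml")))
      }
      if (length(edge_rows))
        emit(do.call(rbind, edge_rows), "network_edges")
      anchor <- find_stable_cag(partitions)
      report <- NULL
      if (length(anchor)) {
        cand <- setdiff(genera, anchor)
        prof <- t(vapply(cand, function(gen)
          anchor_correlation_profile(rel, metadata, anchor, gen),
          stats::setNames(numeric(3), group3_levels())))
        report <- variable_genera(prof, p$variability_threshold)
        emit(report, "anchor_variability")
      }
      emit(data.frame(genus = anchor), "anchor_genera")
      results$network <- list(anchor = anchor, partitions = partitions,
                              variability = report)
    }, error = function(e) stage_fail("network", e))
  }
  if ("cohort_stats" %in% config$stages) {
    tryCatch({
      vars <- setdiff(names(metadata),
                      c("sample_id", "stage6", "group3"))
      vars <- vars[vapply(vars, function(v)
        !is.numeric(metadata[[v]]) &&
          length(unique(metadata[[v]])) > 1, FALSE)]
      if (length(vars)) {
        st <- cohort_covariate_tests(metadata, vars)
        emit(st, "cohort_stats")
        results$cohort_stats <- st
      }
    }, error = function(e) stage_fail("cohort_stats", e))
  }
  summary <- list(package = "enterocag",
                  version = as.character(utils::packageVersion("enterocag")),
                  seed = config$seed, synthetic = config$synthetic,
                  stages = config$stages,
                  parameters = config$params[setdiff(names(config$params),
                                                     "combinations")],
                  combinations = lapply(config$params$combinations,
                                        paste, collapse = "+"),
                  outputs = outputs)
  jsonlite::write_json(summary,
                       file.path(config$outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$summary <- summary
  invisible(results)
}
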