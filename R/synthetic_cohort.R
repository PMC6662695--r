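#' Synthetic cohort configuration
#'
#' Full generative specification of a synthetic faecal-microbiota cohort:
#' a genus panel with three enterotype composition regimes
#' (Bacteroides-dominant, Prevotella-dominant, Escherichia-mixed), planted
#' blocks of co-varying genera (one 10-genus block marked as the stable
#' "anchor"), per-group and per-stage log2 abundance effects, log-scale
#' residual noise, and multinomial sequencing depth.
#'
#' The generative model, per sample: one standard-normal factor is drawn
#' per block; the latent log-abundance of genus g is
#' `profile[enterotype, g] + lambda_b * factor_b` (if g belongs to block
#' b) `+ ln(2) * (group_effect + stage_effect) + Normal(0, noise_sd)`;
#' weights are exponentiated and closed to a composition, and counts drawn
#' `multinomial(depth, composition)`.
#'
#' Enterotype profiles place every non-driver genus at log-mean 0 and set
#' the dominant driver so that the sample clears its classification
#' threshold (Bacteroides >= 40 %, Prevotella >= 30 %) with a margin of
#' two residual standard deviations; the Escherichia driver of the mixed
#' regime is set to a median fraction of ~25 % (no threshold applies to
#' it). See the methods vignette for why the margin, rather than a target
#' mean fraction, anchors the defaults.
#'
#' @param genus_panel ordered genus labels; must contain `Bacteroides`,
#'   `Prevotella`, `Escherichia`.
#' @param blocks named list of disjoint genus-label vectors (the planted
#'   co-abundance blocks).
#' @param block_loadings numeric in `[0,1]`, one per block (recycled).
#' @param anchor name of the block treated as the stable anchor.
#' @param group_effects genera x 3 matrix of log2 shifts, columns
#'   `normal`, `adenoma`, `cancer`; `NULL` for no group effects.
#' @param stage_effects genera x 6 matrix of log2 shifts over
#'   [stage6_levels()]; `NULL` for none.
#' @param noise_sd log-scale residual standard deviation.
#' @param depth expected reads per sample (multinomial size).
#' @param n_per_cell samples per (group3 x enterotype) cell.
#' @param margin_z classification safety margin in units of `noise_sd`.
#' @param block_groups optional named list mapping a block to the
#'   disease groups whose samples express it (the factor loading is
#'   zero elsewhere); blocks absent from the list are expressed in all
#'   groups.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(genus_panel, blocks, block_loadings = 0.8,
                             anchor = names(blocks)[1],
                             group_effects = NULL, stage_effects = NULL,
                             noise_sd = 1.0, depth = 50000, n_per_cell = 20,
                             margin_z = 2.0, block_groups = NULL) {
  drivers <- c("Bacteroides", "Prevotella", "Escherichia")
  if (!all(drivers %in% genus_panel))
    stop("genus_panel must contain Bacteroides, Prevotella and Escherichia")
  if (anyDuplicated(genus_panel)) stop("duplicate genus labels in panel")
  if (is.null(names(blocks)) || anyDuplicated(names(blocks)))
    stop("blocks must be uniquely named")
  all_members <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(all_members)) stop("blocks must be pairwise disjoint")
  if (!all(all_members %in% genus_panel))
    stop("block members must come from genus_panel")
  if (any(drivers %in% all_members))
    stop("enterotype driver genera cannot belong to blocks")
  block_loadings <- rep_len(block_loadings, length(blocks))
  names(block_loadings) <- names(blocks)
  if (any(block_loadings < 0 | block_loadings > 1))
    stop("block loadings must lie in [0, 1]")
  if (!anchor %in% names(blocks)) stop("anchor must name one of the blocks")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (depth < 1) stop("depth must be >= 1")
  if (n_per_cell < 1 || n_per_cell != round(n_per_cell))
    stop("n_per_cell must be a positive integer")
  n_per_cell <- as.integer(n_per_cell)
  zero6 <- function() matrix(0, length(genus_panel), 6,
                             dimnames = list(genus_panel, stage6_levels()))
  zero3 <- function() matrix(0, length(genus_panel), 3,
                             dimnames = list(genus_panel, group3_levels()))
  if (is.null(group_effects)) group_effects <- zero3()
  if (is.null(stage_effects)) stage_effects <- zero6()
  stopifnot(identical(rownames(group_effects), genus_panel),
            identical(colnames(group_effects), group3_levels()),
            identical(rownames(stage_effects), genus_panel),
            identical(colnames(stage_effects), stage6_levels()))
  if (!is.null(block_groups)) {
    if (!all(names(block_groups) %in% names(blocks)))
      stop("block_groups names must match block names")
    if (!all(unlist(block_groups) %in% group3_levels()))
      stop("block_groups values must be disease group labels")
  }
  cfg <- list(genus_panel = genus_panel, blocks = blocks,
              block_loadings = block_loadings, anchor = anchor,
              block_groups = block_groups,
              group_effects = group_effects, stage_effects = stage_effects,
              noise_sd = noise_sd, depth = depth, n_per_cell = n_per_cell,
              margin_z = margin_z,
              enterotype_profiles = enterotype_profiles(
                genus_panel, blocks, block_loadings, noise_sd, margin_z))
  class(cfg) <- "synthetic_config"
  cfg
}

# Per-enterotype base log-mean vectors. Non-driver genera sit at 0; the
# dominant driver is placed so that, given lognormal weight noise of sd
# noise_sd, the sample clears its relative-abundance threshold with a
# margin of margin_z residual sds against the (nearly constant) mass of
# the remaining genera.
enterotype_profiles <- function(genus_panel, blocks, block_loadings,
                                noise_sd, margin_z) {
  p <- length(genus_panel)
  lam <- stats::setNames(numeric(p), genus_panel)
  for (b in names(blocks)) lam[blocks[[b]]] <- block_loadings[b]
  # expected lognormal weight of each genus at log-mean 0
  w <- exp((noise_sd^2 + lam^2) / 2)
  prof <- matrix(0, 3, p, dimnames = list(c("I", "II", "III"), genus_panel))
  other_mass <- function(driver) sum(w[setdiff(genus_panel, driver)])
  # RA_B >= 0.4  <=>  W_B >= (0.4 / 0.6) * other mass
  prof["I", "Bacteroides"] <-
    log(2 / 3 * other_mass("Bacteroides")) + margin_z * noise_sd
  # RA_P >= 0.3  <=>  W_P >= (0.3 / 0.7) * other mass
  prof["II", "Prevotella"] <-
    log(3 / 7 * other_mass("Prevotella")) + margin_z * noise_sd
  # Escherichia-mixed regime: median fraction ~ 1/4, no threshold to clear
  prof["III", "Escherichia"] <- log(other_mass("Escherichia") / 3)
  prof
}

#' Default synthetic cohort configuration
#'
#' A 60-genus panel: the three enterotype drivers plus seven planted
#' co-abundance blocks (lambda = 0.8) covering the remaining 57 genera --
#' a 10-genus anchor block present unchanged in every group, a 5-genus
#' pathogen-like block enriched (+1.5 log2) in the cancer group, a
#' 6-genus butyrate-producer-like block depleted (-1.5 log2) in cancer,
#' and four neutral 9-genus blocks. Stage-specific depletions
#' (Oscillospira from carcinoma in situ onwards, Haemophilus from
#' early-stage carcinoma onwards, -2 log2) exercise the stage-transition
#' analysis. Residual noise sd 1.0 (log scale), depth 50,000 reads per
#' sample, 45 samples per (group x enterotype) cell (405 samples,
#' 135 per group).
#'
#' Every non-driver genus belongs to a block, and the default cell count
#' is the smallest round value at which the planted block structure is
#' reliably recovered from per-group correlation matrices: unstructured
#' filler genera and smaller groups both leave exact cluster recovery to
#' luck, and the generator's purpose is ground truth, not cohort mimicry
#' (see the methods vignette).
#'
#' @param n_per_cell,noise_sd,depth,block_loading overrides for the
#'   corresponding defaults.
#' @param group_effect_log2 absolute log2 cancer shift of the
#'   pathogen-like (+) and butyrate-like (-) blocks; set 0 for a null
#'   cohort.
#' @param stage_effect_log2 absolute log2 depletion of the two
#'   stage-transition genera; set 0 to disable.
#' @return a `synthetic_config`.
#' @export
default_config <- function(n_per_cell = 45, noise_sd = 1.0, depth = 50000,
                           block_loading = 0.8, group_effect_log2 = 1.5,
                           stage_effect_log2 = 2.0) {
  blocks <- list(
    anchor = c("Brenneria", "Cronobacter", "Erwinia", "Nitrobacter",
               "Paracoccus", "Pectobacterium", "Photorhabdus", "Shigella",
               "Sporosarcina", "Serratia"),
    pathogen = c("Fusobacterium", "Enterococcus", "Aeromonas", "Morganella",
                 "Porphyromonas"),
    butyrate = c("Oscillospira", "Roseburia", "Faecalibacterium",
                 "Eubacterium", "Coprococcus", "Ruminococcus"),
    b4 = c("Haemophilus", "Blautia", "Dorea", "Collinsella",
           "Streptococcus", "Veillonella", "Clostridium", "Sutterella",
           "Desulfovibrio"),
    b5 = c("Klebsiella", "Citrobacter", "Enterobacter", "Proteus",
           "Providencia", "Leclercia", "Bilophila", "Peptostreptococcus",
           "Synergistes"),
    b6 = c("Lactobacillus", "Bifidobacterium", "Akkermansia", "Dialister",
           "Megamonas", "Mitsuokella", "Xenorhabdus", "Gemmiger",
           "Phascolarctobacterium"),
    b7 = c("Parabacteroides", "Alistipes", "Odoribacter", "Butyricimonas",
           "Barnesiella", "Paraprevotella", "Tannerella", "Anaerostipes",
           "Coprobacillus"))
  panel <- c("Bacteroides", "Prevotella", "Escherichia",
             unlist(blocks, use.names = FALSE))
  ge <- matrix(0, length(panel), 3,
               dimnames = list(panel, group3_levels()))
  ge[blocks$pathogen, "cancer"] <- +group_effect_log2
  ge[blocks$butyrate, "cancer"] <- -group_effect_log2
  se <- matrix(0, length(panel), 6,
               dimnames = list(panel, stage6_levels()))
  se["Oscillospira", c("crc_stage0", "crc_early", "crc_late")] <-
    -stage_effect_log2
  se["Haemophilus", c("crc_early", "crc_late")] <- -stage_effect_log2
  synthetic_config(genus_panel = panel, blocks = blocks,
                   block_loadings = block_loading, anchor = "anchor",
                   group_effects = ge, stage_effects = se,
                   noise_sd = noise_sd, depth = depth,
                   n_per_cell = n_per_cell)
}

#' Generate a seeded synthetic cohort
#'
#' Draws a count table, cohort metadata and a ground-truth record from a
#' [synthetic_config()]. Identical `(config, seed)` pairs give identical
#' output. Within the adenoma and cancer groups, samples cycle through
#' the constituent pathology stages (small/advanced adenoma; stage 0 /
#' early / late carcinoma).
#'
#' @param config a `synthetic_config`; default [default_config()].
#' @param seed integer RNG seed.
#' @return a list with elements `table` (counts [genus_table()]),
#'   `metadata` ([cohort_metadata()]) and `truth` (list with per-sample
#'   `samples` data.frame and per-genus `genera` data.frame).
#' @export
generate_cohort <- function(config = default_config(), seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(as.integer(seed))
  panel <- config$genus_panel
  p <- length(panel)
  groups <- group3_levels()
  ets <- c("I", "II", "III")
  stage_cycle <- list(
    normal = "normal",
    adenoma = c("small_adenoma", "advanced_adenoma"),
    cancer = c("crc_stage0", "crc_early", "crc_late"))
  samples <- expand.grid(idx = seq_len(config$n_per_cell),
                         enterotype = ets, group3 = groups,
                         stringsAsFactors = FALSE)
  samples$stage6 <- unlist(lapply(groups, function(g)
    rep_len(stage_cycle[[g]], 3 * config$n_per_cell)))
  n <- nrow(samples)
  samples$sample_id <- sprintf("S%03d", seq_len(n))
  lam <- stats::setNames(numeric(p), panel)
  member_of <- stats::setNames(rep(NA_character_, p), panel)
  for (b in names(config$blocks)) {
    lam[config$blocks[[b]]] <- config$block_loadings[b]
    member_of[config$blocks[[b]]] <- b
  }
  counts <- matrix(0L, n, p, dimnames = list(samples$sample_id, panel))
  for (i in seq_len(n)) {
    mu <- config$enterotype_profiles[samples$enterotype[i], ] +
      log(2) * (config$group_effects[, samples$group3[i]] +
                  config$stage_effects[, samples$stage6[i]])
    f <- stats::rnorm(length(config$blocks))
    names(f) <- names(config$blocks)
    idx <- member_of
    idx[is.na(idx)] <- names(f)[1]  # lambda is 0 there, term vanishes
    lam_i <- lam
    if (!is.null(config$block_groups)) {
      for (b in names(config$block_groups))
        if (!samples$group3[i] %in% config$block_groups[[b]])
          lam_i[config$blocks[[b]]] <- 0
    }
    factor_term <- lam_i * f[idx]
    logw <- mu + factor_term + stats::rnorm(p, 0, config$noise_sd)
    w <- exp(logw - max(logw))
    counts[i, ] <- stats::rmultinom(1, config$depth, w / sum(w))
  }
  metadata <- cohort_metadata(
    data.frame(sample_id = samples$sample_id, stage6 = samples$stage6,
               stringsAsFactors = FALSE))
  truth <- list(
    samples = data.frame(sample_id = samples$sample_id,
                         enterotype = samples$enterotype,
                         group3 = samples$group3, stage6 = samples$stage6,
                         stringsAsFactors = FALSE),
    genera = data.frame(genus = panel, block = unname(member_of),
                        anchor = unname(!is.na(member_of) &
                                          member_of == config$anchor),
                        cancer_log2_effect =
                          unname(config$group_effects[, "cancer"]),
                        stringsAsFactors = FALSE),
    seed = as.integer(seed))
  list(table = genus_table(counts, kind = "counts"),
       metadata = metadata, truth = truth)
}

#' Write a generated cohort to disk
#'
#' Emits the count table (TSV), metadata (TSV) and ground truth (JSON,
#' seed included) under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(dir, "abundance_counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_abundance_table(cohort$table, paths["table"], "tsv")
  utils::write.table(as.data.frame(cohort$metadata), paths["metadata"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
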