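#' Thresholded Pearson correlation network
#'
#' Builds an undirected weighted network over genera: an edge connects
#' two genera when the absolute Pearson correlation of their relative
#' abundances (over the chosen samples) reaches `edge_threshold`.
#' Constant genera are excluded with a warning.
#'
#' @param table relative [genus_table()].
#' @param sample_subset sample ids (default all; >= 3 required).
#' @param genus_subset genus names (default all).
#' @param edge_threshold minimum `|r|` for an edge (default 0.5).
#' @param group,stratum optional provenance labels stored on the result.
#' @return a `correlation_network`: list with `nodes`, `edges`
#'   (data.frame genus_a, genus_b, r; each unordered pair once),
#'   `edge_threshold`, `group`, `stratum`.
#' @export
pearson_network <- function(table, sample_subset = rownames(table),
                            genus_subset = colnames(table),
                            edge_threshold = 0.5,
                            group = NA_character_,
                            stratum = NA_character_) {
  stopifnot(inherits(table, "genus_table"))
  if (length(sample_subset) < 3) stop("need at least 3 samples")
  m <- unclass(table)[sample_subset, genus_subset, drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant genus/genera: ",
            paste(genus_subset[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  r <- stats::cor(m, method = "pearson")
  idx <- which(upper.tri(r) & abs(r) >= edge_threshold, arr.ind = TRUE)
  edges <- data.frame(genus_a = colnames(r)[idx[, 1]],
                      genus_b = colnames(r)[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  structure(list(nodes = colnames(r), edges = edges,
                 edge_threshold = edge_threshold,
                 group = group, stratum = stratum),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d edges (|r| >= %g)\n",
              length(x$nodes), nrow(x$edges), x$edge_threshold))
  invisible(x)
}

#' Write a correlation network to GraphML and edge-list TSV
#'
#' @param network a `correlation_network`.
#' @param graphml_path optional GraphML output path.
#' @param tsv_path optional edge-list TSV path (genus_a, genus_b, r,
#'   group, stratum).
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, graphml_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(network, "correlation_network"))
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = data.frame(
                                         name = network$nodes))
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(tsv_path)) {
    df <- network$edges
    df$group <- network$group
    df$stratum <- network$stratum
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml = graphml_path, tsv = tsv_path))
}

#' Find the co-abundance group stable across all partitions
#'
#' Returns the largest cluster whose member set is *identical* in every
#' supplied partition (the strict reading of a cluster "staying the
#' same" across disease groups and enterotypes); ties are broken by the
#' lexicographically smallest member. An optional relaxed mode accepts
#' clusters matching across partitions at Jaccard similarity >=
#' `jaccard` instead of exact identity (the returned set is then the one
#' from the first partition).
#'
#' @param partitions list of `cag_partition` objects (length >= 2) over
#'   a shared genus universe.
#' @param relaxed use Jaccard matching instead of exact identity.
#' @param jaccard similarity threshold for the relaxed mode.
#' @return character vector of anchor genera (possibly empty).
#' @export
find_stable_cag <- function(partitions, relaxed = FALSE, jaccard = 0.8) {
  stopifnot(length(partitions) >= 2)
  universes <- lapply(partitions, function(p) p$genus)
  if (!length(Reduce(intersect, universes)))
    stop("partitions share no genera")
  clusters_of <- function(p) split(p$genus, p$cag)
  ref <- clusters_of(partitions[[1]])
  others <- lapply(partitions[-1], clusters_of)
  match_fun <- if (relaxed) {
    function(set, cls) any(vapply(cls, function(cl) {
      length(intersect(set, cl)) / length(union(set, cl)) >= jaccard
    }, FALSE))
  } else {
    function(set, cls) any(vapply(cls, function(cl)
      setequal(set, cl), FALSE))
  }
  stable <- Filter(function(set)
    all(vapply(others, function(cls) match_fun(set, cls), FALSE)), ref)
  if (!length(stable)) return(character(0))
  sizes <- lengths(stable)
  best <- stable[sizes == max(sizes)]
  firsts <- vapply(best, function(s) min(sort(s)), "")
  sort(best[[order(firsts)[1]]])
}

#' Per-group correlation of a genus with the anchor CAG
#'
#' For each disease group, the mean Pearson correlation (over that
#' group's samples) between the genus and every anchor member. Groups in
#' which the genus (or an anchor member) is constant yield `NA` and are
#' excluded from variability scoring downstream.
#'
#' @param table relative [genus_table()].
#' @param metadata [cohort_metadata()].
#' @param anchor character vector of anchor genera.
#' @param genus single genus not in the anchor.
#' @return named numeric vector, one mean correlation per group3 level
#'   present.
#' @export
anchor_correlation_profile <- function(table, metadata, anchor, genus) {
  if (genus %in% anchor) stop("genus must not belong to the anchor")
  missing <- setdiff(c(anchor, genus), colnames(table))
  if (length(missing))
    stop("genus/genera missing from table: ", paste(missing, collapse = ", "))
  g3 <- metadata$group3[match(rownames(table), metadata$sample_id)]
  groups <- intersect(group3_levels(), unique(g3))
  out <- stats::setNames(rep(NA_real_, length(groups)), groups)
  for (grp in groups) {
    ids <- rownames(table)[g3 == grp]
    if (length(ids) < 3) next
    v <- unclass(table)[ids, genus]
    if (stats::sd(v) == 0) next
    rs <- vapply(anchor, function(a) {
      av <- unclass(table)[ids, a]
      if (stats::sd(av) == 0) NA_real_ else stats::cor(v, av)
    }, 0)
    out[grp] <- mean(rs, na.rm = TRUE)
  }
  out
}

#' Flag genera whose anchor correlation varies between groups
#'
#' The variability score of a genus is the range (max minus min) of its
#' per-group anchor correlations; genera scoring at or above the
#' threshold are flagged, sorted by score descending.
#'
#' @param profiles matrix or data.frame, genera in rows, groups in
#'   columns, of per-group anchor correlations (`NA` = undefined).
#' @param variability_threshold flagging threshold (default 0.4).
#' @return data.frame `genus`, `score`, `flagged`, sorted by score.
#' @export
variable_genera <- function(profiles, variability_threshold = 0.4) {
  profiles <- as.matrix(profiles)
  if (!nrow(profiles))
    return(data.frame(genus = character(), score = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  score <- apply(profiles, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    max(v) - min(v)
  })
  out <- data.frame(genus = rownames(profiles), score = score,
                    flagged = !is.na(score) & score >= variability_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  out
}
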