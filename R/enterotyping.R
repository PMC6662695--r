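#' Assign an enterotype by the Bacteroides/Prevotella threshold rule
#'
#' A sample's enterotype is determined solely by the relative abundances
#' of Bacteroides (`RA_B`) and Prevotella (`RA_P`):
#'
#' * enterotype I:  `RA_B >= 0.40` and `RA_B > RA_P`;
#' * enterotype II: `RA_P >= 0.30` and `RA_P >= RA_B`;
#' * enterotype III: everything else (in practice an Escherichia-mixed
#'   community).
#'
#' Rule I is tested first, then rule II; the two are mutually exclusive by
#' construction (I requires `RA_B > RA_P`, II requires `RA_P >= RA_B`).
#' Genera absent from the composition are read as zero.
#'
#' @param composition named numeric vector of relative abundances summing
#'   to 1 (within 1e-6).
#' @return a list of class `enterotype_label` with elements `label`
#'   (factor `"I"`/`"II"`/`"III"`), `ra_b` and `ra_p`.
#' @export
assign_enterotype <- function(composition) {
  if (any(composition < 0)) stop("negative relative abundance")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition must sum to 1 (got ", format(sum(composition)), ")")
  ra_b <- if ("Bacteroides" %in% names(composition))
    unname(composition[["Bacteroides"]]) else 0
  ra_p <- if ("Prevotella" %in% names(composition))
    unname(composition[["Prevotella"]]) else 0
  label <- if (ra_b >= 0.40 && ra_b > ra_p) "I"
  else if (ra_p >= 0.30 && ra_p >= ra_b) "II"
  else "III"
  structure(list(label = factor(label, levels = c("I", "II", "III")),
                 ra_b = ra_b, ra_p = ra_p),
            class = "enterotype_label")
}

#' @export
print.enterotype_label <- function(x, ...) {
  cat(sprintf("enterotype %s (RA_B = %.4f, RA_P = %.4f)\n",
              as.character(x$label), x$ra_b, x$ra_p))
  invisible(x)
}

#' Enterotype every sample of a cohort
#'
#' Applies [assign_enterotype()] to each row of a relative abundance table
#' and cross-tabulates the labels against the three disease groups.
#'
#' @param table a relative [genus_table()].
#' @param metadata optional [cohort_metadata()] covering all samples; when
#'   supplied, a group3 x enterotype contingency matrix is attached.
#' @return a data.frame (`sample_id`, `enterotype`, `ra_b`, `ra_p`), with
#'   attribute `contingency` when metadata was given.
#' @export
enterotype_cohort <- function(table, metadata = NULL) {
  stopifnot(inherits(table, "genus_table"))
  if (!identical(table_kind(table), "relative"))
    stop("enterotype_cohort requires a relative table; see to_relative()")
  if (!is.null(metadata)) {
    missing <- setdiff(rownames(table), metadata$sample_id)
    if (length(missing) == nrow(table))
      stop("no overlap between table samples and metadata")
    if (length(missing))
      stop("sample(s) missing from metadata: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  labels <- lapply(rownames(table), function(s)
    assign_enterotype(unclass(table)[s, ]))
  out <- data.frame(
    sample_id = rownames(table),
    enterotype = factor(vapply(labels, function(l) as.character(l$label), ""),
                        levels = c("I", "II", "III")),
    ra_b = vapply(labels, function(l) l$ra_b, 0),
    ra_p = vapply(labels, function(l) l$ra_p, 0),
    stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    g <- factor(metadata$group3[match(out$sample_id, metadata$sample_id)],
                levels = group3_levels())
    attr(out, "contingency") <- table(group3 = g, enterotype = out$enterotype)
  }
  out
}

#' Principal coordinates ordination of a cohort
#'
#' Classical metric scaling of pairwise Bray-Curtis (default) or
#' Jensen-Shannon distances between samples of a relative abundance
#' table. Purely descriptive: enterotype assignment never depends on the
#' ordination. Negative eigenvalues are clipped to zero when computing
#' explained-variance fractions.
#'
#' @param table a relative [genus_table()] with at least 3 samples.
#' @param distance `"bray_curtis"` or `"jensen_shannon"`.
#' @param k number of axes returned.
#' @return list with `coordinates` (samples x k matrix), `eig`
#'   (all eigenvalues) and `variance_fraction` (per returned axis).
#' @export
pcoa_ordination <- function(table, distance = c("bray_curtis",
                                                "jensen_shannon"),
                            k = 2) {
  stopifnot(inherits(table, "genus_table"))
  distance <- match.arg(distance)
  if (nrow(table) < 3) stop("ordination requires at least 3 samples")
  m <- unclass(to_relative(table))
  d <- switch(distance,
              bray_curtis = vegan::vegdist(m, method = "bray"),
              jensen_shannon = jsd_dist(m))
  k <- min(k, nrow(m) - 1)
  # cmdscale warns when fewer than k eigenvalues are positive; the full
  # eigenvalue vector is returned to the caller instead
  sc <- suppressWarnings(stats::cmdscale(d, k = nrow(m) - 1, eig = TRUE))
  eig <- sc$eig
  pos <- pmax(eig, 0)
  k <- min(k, ncol(sc$points))
  coords <- sc$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(k))
  list(coordinates = coords, eig = eig,
       variance_fraction = pos[seq_len(k)] / sum(pos),
       distance = distance)
}

# square root of the Jensen-Shannon divergence (a metric), natural log
jsd_dist <- function(m) {
  n <- nrow(m)
  xlx <- function(v) ifelse(v > 0, v * log(v), 0)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- m[i, ]; q <- m[j, ]; mid <- (p + q) / 2
    jsd <- sum(xlx(p) + xlx(q)) / 2 - sum(xlx(mid))
    d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
  }
  stats::as.dist(d)
}
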