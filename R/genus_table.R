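#' Genus-level abundance table
#'
#' The central container of the package: a samples x genera matrix of
#' non-negative abundances, either raw read counts (`kind = "counts"`) or
#' relative abundances whose rows sum to one (`kind = "relative"`).
#' Sample identifiers are the row names, genus labels the column names;
#' both must be unique.
#'
#' @param values numeric matrix, samples in rows, genera in columns, with
#'   row and column names set.
#' @param kind `"counts"` or `"relative"`.
#' @return An object of class `genus_table` (a validated matrix with a
#'   `kind` attribute).
#' @export
genus_table <- function(values, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  attr(values, "kind") <- kind
  class(values) <- c("genus_table", "matrix")
  validate_genus_table(values)
  values
}

#' Validate a genus_table
#'
#' Checks the container invariants: no missing values, non-negative
#' entries, unique sample and genus names, and rows summing to one (within
#' 1e-9) when `kind = "relative"`.
#'
#' @param x a `genus_table`.
#' @return `x`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_genus_table <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("genus_table requires sample ids (rownames) and genus names (colnames)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate genus names: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop("genus_table contains missing values")
  if (any(x < 0)) stop("genus_table contains negative values")
  if (identical(table_kind(x), "relative")) {
    rs <- rowSums(x)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad))
      stop("relative abundance rows must sum to 1 (off by > 1e-9): ",
           paste(utils::head(rownames(x)[bad], 5), collapse = ", "))
  }
  invisible(x)
}

#' @rdname genus_table
#' @param x a `genus_table`.
#' @export
table_kind <- function(x) attr(x, "kind")

#' @export
print.genus_table <- function(x, ...) {
  cat(sprintf("genus_table [%s]: %d samples x %d genera\n",
              table_kind(x), nrow(x), ncol(x)))
  cat("samples:", paste(utils::head(rownames(x), 3), collapse = ", "),
      if (nrow(x) > 3) "..." else "", "\n")
  cat("genera: ", paste(utils::head(colnames(x), 5), collapse = ", "),
      if (ncol(x) > 5) "..." else "", "\n")
  invisible(x)
}

#' Read a genus abundance table from TSV or BIOM
#'
#' TSV layout: UTF-8, tab-delimited, header row of genus names, first
#' column holding the sample id (samples in rows). Set `transpose = TRUE`
#' for tables exported genera-in-rows. BIOM files are read with the
#' biomformat package (native orientation: observations in rows) and
#' transposed into samples-in-rows.
#'
#' The table kind is inferred: all entries integer-valued means counts;
#' every row summing to 1 within 0.01 means relative abundances. Tables
#' matching neither (or, ambiguously, an integer table whose rows also sum
#' to one) are rejected rather than guessed at.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param transpose logical; TSV only, set when genera are in rows.
#' @return a validated [genus_table()].
#' @export
read_abundance_table <- function(path, format = c("tsv", "biom"),
                                 transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed TSV (need id column + >=1 genus): ", path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m))
      stop("malformed TSV: non-numeric abundance field in ", path)
    rownames(m) <- ids
    if (transpose) m <- t(m)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
  }
  genus_table(m, kind = infer_kind(m))
}

infer_kind <- function(m) {
  integral <- all(abs(m - round(m)) < 1e-9)
  rel <- all(abs(rowSums(m) - 1) <= 0.01)
  if (integral && !rel) return("counts")
  if (rel && !integral) return("relative")
  if (integral && rel)
    stop("ambiguous table: integer-valued with unit row sums; ",
         "construct with genus_table() and an explicit kind")
  stop("cannot infer table kind: neither integer counts nor rows summing to 1")
}

#' Write a genus abundance table
#'
#' Inverse of [read_abundance_table()]; the TSV writer emits samples in
#' rows with the sample id in the first column (`sample_id`).
#'
#' @param x a `genus_table`.
#' @param path output path.
#' @param format `"tsv"` or `"biom"`.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM files requires the biomformat package")
    b <- biomformat::make_biom(t(unclass(x)))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Merge an OTU table to genus level
#'
#' Sums, within each sample, the abundances of all OTUs assigned the same
#' genus label. OTUs absent from the taxonomy map are routed to a reserved
#' `"unclassified"` genus rather than dropped, so per-sample totals are
#' conserved exactly.
#'
#' @param otu_values non-negative matrix, samples in rows, OTU ids in
#'   columns.
#' @param taxonomy named character vector mapping OTU id to genus label.
#' @param unassigned label used for OTUs missing from `taxonomy`.
#' @return a [genus_table()] of kind `"counts"` if the input is
#'   integer-valued, else the column-summed matrix with the input treated
#'   as counts-like (merging a relative table is not meaningful).
#' @export
merge_to_genus <- function(otu_values, taxonomy, unassigned = "unclassified") {
  otu_values <- as.matrix(otu_values)
  if (length(taxonomy) == 0) stop("empty taxonomy map")
  if (is.null(colnames(otu_values))) stop("otu_values must have OTU id columns")
  genus <- taxonomy[colnames(otu_values)]
  genus[is.na(genus)] <- unassigned
  groups <- factor(genus, levels = unique(genus))
  merged <- t(rowsum(t(otu_values), groups))
  colnames(merged) <- levels(groups)
  rownames(merged) <- rownames(otu_values)
  genus_table(merged, kind = "counts")
}

#' Convert counts to relative abundances
#'
#' Divides every sample row by its total. Rows of the result sum to one
#' within 1e-9.
#'
#' @param x a `genus_table` of kind `"counts"` (a relative table is
#'   returned unchanged, making the operation idempotent).
#' @return a `genus_table` of kind `"relative"`.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "genus_table"))
  if (identical(table_kind(x), "relative")) return(x)
  rs <- rowSums(x)
  if (any(rs <= 0))
    stop("all-zero sample row(s): ",
         paste(rownames(x)[rs <= 0], collapse = ", "))
  genus_table(unclass(x) / rs, kind = "relative")
}

#' Per-genus prevalence in a sample subset
#'
#' Fraction of the subset's samples in which each genus is detected
#' (abundance strictly greater than zero).
#'
#' @param x a `genus_table`.
#' @param sample_subset character vector of sample ids; default all
#'   samples.
#' @return named numeric vector over genera, values in `[0, 1]`.
#' @export
prevalence <- function(x, sample_subset = rownames(x)) {
  stopifnot(inherits(x, "genus_table"))
  if (length(sample_subset) == 0) stop("empty sample subset")
  missing <- setdiff(sample_subset, rownames(x))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  colMeans(unclass(x)[sample_subset, , drop = FALSE] > 0)
}

#' Binary-logarithm transform with explicit zero policy
#'
#' Used for log-scale presentation of richness and relative abundance.
#' Zeros are either dropped or replaced by half the smallest positive
#' value of the vector (the usual compositional pseudocount) before
#' taking log2.
#'
#' @param values non-negative numeric vector.
#' @param zero_policy `"pseudocount"` (default) or `"drop"`.
#' @return transformed numeric vector (shorter than the input under
#'   `"drop"` when zeros are present).
#' @export
log2_transform <- function(values, zero_policy = c("pseudocount", "drop")) {
  zero_policy <- match.arg(zero_policy)
  if (any(values < 0)) stop("negative values cannot be log-transformed")
  if (zero_policy == "drop") return(log2(values[values > 0]))
  if (!any(values > 0))
    stop("all-zero input: no positive minimum for the pseudocount")
  pc <- min(values[values > 0]) / 2
  log2(ifelse(values == 0, pc, values))
}
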