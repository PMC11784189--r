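# ASV count-table processing: low-count and off-target filtering,
# per-sample relative abundance, replicate means, clade-level aggregation,
# and the relative -> absolute AMF conversion against qPCR fungal DNA
# quantities.
#
# Count tables are integer matrices with samples as rows and ASVs as
# columns (both axes named); abundance tables are the same shape with rows
# summing to 1.

validate_count_table <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("sample and ASV names must be unique")
  if (any(counts < 0)) stop("negative counts")
  invisible(counts)
}

drop_empty_samples <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning("dropping sample(s) with zero total: ",
            paste(rownames(counts)[tot == 0], collapse = ", "))
    counts <- counts[tot > 0, , drop = FALSE]
  }
  counts
}

#' Read/write a count table TSV
#'
#' Samples as rows, ASVs as columns; the first column holds sample ids.
#'
#' @param path file path.
#' @return an integer matrix (samples x ASVs).
#' @export
read_count_table <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  validate_count_table(m)
  m
}

#' @rdname read_count_table
#' @param counts a count (or abundance) matrix.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  write_tsv(df, path)
}

#' Read sample metadata
#'
#' TSV with columns sample_id, genotype, treatment, replicate; the
#' (genotype, treatment, replicate) triple must be unique.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_sample_meta <- function(path) {
  meta <- read_tsv(path)
  need <- c("sample_id", "genotype", "treatment", "replicate")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0)
    stop("metadata missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(meta[c("genotype", "treatment", "replicate")]))
    stop("duplicate (genotype, treatment, replicate) in metadata")
  meta
}

#' Remove singleton/doubleton ASVs
#'
#' Removes every ASV whose dataset-wide total count is at most `max_total`
#' (default 2: singletons and doubletons).  Column order is otherwise
#' preserved; samples left with zero total are dropped with a warning.
#'
#' @param counts a count matrix (samples x ASVs).
#' @param max_total largest dataset-wide total to remove.
#' @return a list with elements `counts` (filtered matrix) and `removed`
#'   (character vector of removed ASV ids).
#' @export
filter_low_count <- function(counts, max_total = 2) {
  validate_count_table(counts)
  tot <- colSums(counts)
  removed <- colnames(counts)[tot <= max_total]
  kept <- counts[, tot > max_total, drop = FALSE]
  if (ncol(kept) == 0) stop("no ASVs remain after low-count filtering")
  list(counts = drop_empty_samples(kept), removed = removed)
}

#' Drop named ASVs from a count table
#'
#' @param counts a count matrix.
#' @param ids ASV ids to remove (must exist in the table).
#' @return the reduced count matrix; samples left with zero total are
#'   dropped with a warning.
#' @export
drop_asvs <- function(counts, ids) {
  validate_count_table(counts)
  unknown <- setdiff(ids, colnames(counts))
  if (length(unknown) > 0)
    stop("unknown ASV id(s): ", paste(unknown, collapse = ", "))
  kept <- counts[, !(colnames(counts) %in% ids), drop = FALSE]
  if (ncol(kept) == 0) stop("no ASVs remain")
  drop_empty_samples(kept)
}

#' Per-sample relative abundance
#'
#' Each count is divided by its sample total, so every retained row sums to
#' 1.  Samples with zero total are dropped with a warning.
#'
#' @param counts a count matrix.
#' @return a numeric matrix of fractions with the same axes.
#' @export
relative_abundance <- function(counts) {
  validate_count_table(counts)
  counts <- drop_empty_samples(counts)
  sweep(counts, 1, rowSums(counts), "/")
}

#' Mean abundance over biological replicates
#'
#' Unweighted arithmetic mean of the per-sample relative abundances within
#' each (genotype, treatment) group; group rows sum to 1.  Groups with no
#' samples are absent from the output.
#'
#' @param ab an abundance matrix (samples x ASVs).
#' @param meta sample metadata (see [read_sample_meta()]); every sample in
#'   `ab` must have a metadata row.
#' @return a matrix with one row per (genotype, treatment) group, row names
#'   `"genotype:treatment"`, and a `groups` attribute data.frame (genotype,
#'   treatment, n_replicates).
#' @export
replicate_mean <- function(ab, meta) {
  missing <- setdiff(rownames(ab), meta$sample_id)
  if (length(missing) > 0)
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  m <- meta[match(rownames(ab), meta$sample_id), , drop = FALSE]
  key <- paste(m$genotype, m$treatment, sep = ":")
  groups <- unique(key)
  out <- t(vapply(groups, function(g) colMeans(ab[key == g, , drop = FALSE]),
                  numeric(ncol(ab))))
  rownames(out) <- groups
  colnames(out) <- colnames(ab)
  info <- data.frame(genotype = sub(":.*$", "", groups),
                     treatment = sub("^.*:", "", groups),
                     n_replicates = as.integer(table(key)[groups]))
  attr(out, "groups") <- info
  out
}

#' Aggregate abundances to clade level
#'
#' Sums the abundances of the member ASVs of each clade.  The clade label
#' of an ASV is its `novel_clade_id` when present, otherwise its assigned
#' taxon.  Every ASV in the table must have an assignment.
#'
#' @param ab an abundance matrix (samples or groups x ASVs).
#' @param assignments an assignment table covering all ASVs in `ab`.
#' @return an abundance matrix with one column per clade label; rows still
#'   sum to 1.
#' @export
aggregate_by_clade <- function(ab, assignments) {
  missing <- setdiff(colnames(ab), assignments$asv_id)
  if (length(missing) > 0)
    stop("ASV(s) without assignment: ", paste(missing, collapse = ", "))
  a <- assignments[match(colnames(ab), assignments$asv_id), , drop = FALSE]
  label <- ifelse(is.na(a$novel_clade_id), a$taxon, a$novel_clade_id)
  labels <- unique(label)
  out <- vapply(labels, function(l) rowSums(ab[, label == l, drop = FALSE]),
                numeric(nrow(ab)))
  if (nrow(ab) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(ab), labels))
  colnames(out) <- labels
  rownames(out) <- rownames(ab)
  out
}

#' Convert relative AMF abundance to absolute DNA quantity
#'
#' Multiplies the total fungal DNA measured by qPCR by the fraction of
#' Glomeromycota reads among total fungal reads, per sample.
#'
#' @param qpcr a data.frame with columns sample_id, fungal_dna_pg (pg per
#'   reaction, >= 0) and glomero_fraction (in \[0, 1\]).
#' @return named numeric vector of pg AMF DNA per reaction.
#' @export
absolute_amf <- function(qpcr) {
  need <- c("sample_id", "fungal_dna_pg", "glomero_fraction")
  missing <- setdiff(need, names(qpcr))
  if (length(missing) > 0)
    stop("qPCR table missing columns: ", paste(missing, collapse = ", "))
  if (any(qpcr$fungal_dna_pg < 0)) stop("fungal_dna_pg must be >= 0")
  if (any(qpcr$glomero_fraction < 0 | qpcr$glomero_fraction > 1))
    stop("glomero_fraction must be in [0, 1]")
  stats::setNames(qpcr$fungal_dna_pg * qpcr$glomero_fraction, qpcr$sample_id)
}
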