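# Multiple-sequence-alignment operations.  Alignments are consumed, not
# computed: the class wraps a character matrix (rows = sequences, columns =
# alignment sites, gap = "-").  Column indices in the public interface are
# 1-based and windows are closed intervals [start, end], the natural R
# convention.

#' Construct an alignment object
#'
#' @param seqs a named character vector of equal-length gapped sequences, or
#'   a character matrix with row names (one character per cell).
#' @return an object of class `amf_msa` (a character matrix of single
#'   uppercase characters with unique row names).
#' @export
msa <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    stopifnot(is.character(seqs), !is.null(names(seqs)))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1)
      stop("alignment rows have unequal lengths: ",
           paste(range(lens), collapse = "-"))
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("alignment row ids must be present and unique")
  if (ncol(mat) == 0) stop("alignment has zero columns")
  allgap <- rowSums(mat != "-") == 0
  if (any(allgap))
    stop("row(s) with no residues: ", paste(rownames(mat)[allgap], collapse = ", "))
  structure(mat, class = c("amf_msa", "matrix", "array"))
}

#' @export
print.amf_msa <- function(x, ...) {
  cat(sprintf("amf_msa: %d sequences x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read/write a gapped FASTA alignment
#'
#' @param path file path.
#' @return `read_msa` returns an `amf_msa`; `write_msa` returns the path.
#' @export
read_msa <- function(path) {
  msa(read_fasta(path))
}

#' @param x an `amf_msa`.
#' @rdname read_msa
#' @export
write_msa <- function(x, path) {
  write_fasta(msa_strings(x), path)
}

#' Collapse an alignment back to per-row gapped strings
#' @param x an `amf_msa`.
#' @return named character vector of gapped sequences.
#' @export
msa_strings <- function(x) {
  stats::setNames(apply(unclass(x), 1, paste, collapse = ""), rownames(x))
}

#' Per-column gap fraction
#'
#' @param x an `amf_msa`.
#' @return numeric vector of length `ncol(x)`: fraction of rows with a gap
#'   in each column.
#' @export
column_gap_fraction <- function(x) {
  stopifnot(inherits(x, "amf_msa"))
  colMeans(unclass(x) == "-")
}

#' Define a primer pair
#'
#' Both primers are given as written 5'->3'; the reverse primer is matched
#' as its reverse complement on the forward strand.  The defaults are the
#' Glomeromycota-specific AML1/AML2 pair targeting the V3-V4-V5 region of
#' the 18S rRNA gene.
#'
#' @param forward,reverse primer sequences (IUPAC DNA).
#' @param max_mismatches maximum Hamming mismatches tolerated per site.
#' @export
primer_pair <- function(forward = "ATCAACTTTCGATGGTAGGATAGA",
                        reverse = "GAACCCAAACACTTTGGTTTCC",
                        max_mismatches = 2L) {
  forward <- toupper(gsub("[^A-Za-z]", "", forward))
  reverse <- toupper(gsub("[^A-Za-z]", "", reverse))
  stopifnot(nzchar(forward), nzchar(reverse),
            max_mismatches >= 0, max_mismatches < min(nchar(forward), nchar(reverse)))
  structure(list(forward = forward, reverse = reverse,
                 max_mismatches = as.integer(max_mismatches)),
            class = "amf_primer_pair")
}

# Hamming scan of `pattern` along ungapped sequence `s`; returns the
# 1-based start of the best (lowest-mismatch) match, preferring the first
# (from_end = FALSE) or last (from_end = TRUE) best position, or NA if the
# best exceeds max_mm.  IUPAC ambiguity in the pattern matches any base it
# denotes.
hamming_find <- function(s, pattern, max_mm, from_end = FALSE) {
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  np <- length(pc)
  n <- length(sc)
  if (n < np) return(NA_integer_)
  iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                     R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                     W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                     B = c("C", "G", "T"), D = c("A", "G", "T"),
                     H = c("A", "C", "T"), V = c("A", "C", "G"),
                     N = c("A", "C", "G", "T"))
  starts <- seq_len(n - np + 1L)
  mm <- vapply(starts, function(p) {
    sum(vapply(seq_len(np), function(k) !(sc[p + k - 1L] %in% iupac_sets[[pc[k]]]), logical(1)))
  }, numeric(1))
  best <- min(mm)
  if (best > max_mm) return(NA_integer_)
  hits <- starts[mm == best]
  if (from_end) hits[length(hits)] else hits[1]
}

#' Locate the amplicon window bounded by a primer pair
#'
#' Finds, per alignment row, the forward-primer site and the
#' reverse-complemented reverse-primer site on the ungapped sequence
#' (Hamming matching, up to `max_mismatches` mismatches), maps the match
#' offsets through each row's gap pattern to alignment columns, and returns
#' the consensus window as the median per-row start/end column over matching
#' rows.  The window includes both primer-binding regions.
#'
#' @param x an `amf_msa`.
#' @param primers an [primer_pair()].
#' @param min_fraction minimum fraction of rows that must match both
#'   primers for the window to be considered localizable.
#' @return integer vector `c(start, end)`: 1-based, inclusive alignment
#'   columns.
#' @export
locate_primer_window <- function(x, primers = primer_pair(), min_fraction = 0.5) {
  stopifnot(inherits(x, "amf_msa"), inherits(primers, "amf_primer_pair"))
  rc_rev <- revcomp(primers$reverse)
  n_rev <- nchar(rc_rev)
  starts <- ends <- rep(NA_integer_, nrow(x))
  for (i in seq_len(nrow(x))) {
    row <- unclass(x)[i, ]
    res_cols <- which(row != "-")
    s <- paste(row[res_cols], collapse = "")
    pf <- hamming_find(s, primers$forward, primers$max_mismatches, from_end = FALSE)
    pr <- hamming_find(s, rc_rev, primers$max_mismatches, from_end = TRUE)
    if (!is.na(pf) && !is.na(pr)) {
      starts[i] <- res_cols[pf]
      ends[i] <- res_cols[pr + n_rev - 1L]
    }
  }
  ok <- !is.na(starts)
  if (mean(ok) < min_fraction)
    stop(sprintf("primer region not localizable: only %d/%d rows match both primers",
                 sum(ok), length(ok)))
  window <- c(start = as.integer(round(stats::median(starts[ok]))),
              end = as.integer(round(stats::median(ends[ok]))))
  if (window[1] > window[2]) stop("inconsistent primer orientation in alignment")
  window
}

#' Trim an alignment to a column window
#'
#' @param x an `amf_msa`.
#' @param window integer `c(start, end)`, 1-based inclusive columns.
#' @return the trimmed `amf_msa`; rows that become all-gap are dropped with
#'   a warning.
#' @export
trim_to_window <- function(x, window) {
  stopifnot(inherits(x, "amf_msa"), length(window) == 2)
  start <- as.integer(window[1]); end <- as.integer(window[2])
  if (start < 1 || end > ncol(x) || start > end)
    stop(sprintf("invalid window [%d, %d] for alignment with %d columns",
                 start, end, ncol(x)))
  mat <- unclass(x)[, start:end, drop = FALSE]
  allgap <- rowSums(mat != "-") == 0
  if (any(allgap)) {
    warning("dropping all-gap row(s) after trimming: ",
            paste(rownames(mat)[allgap], collapse = ", "))
    mat <- mat[!allgap, , drop = FALSE]
    if (nrow(mat) == 0) stop("all rows became gap-only in the window")
  }
  msa(mat)
}

#' Remove alignment columns by gap-fraction stringency
#'
#' With `max_gap_fraction = t > 0`, every column with gap fraction `>= t` is
#' removed (so retained columns have gap fraction `< t`).  With
#' `max_gap_fraction = 0`, any column containing a gap is removed.  Removed
#' column sets are therefore nested across decreasing thresholds.
#'
#' @param x an `amf_msa`.
#' @param max_gap_fraction threshold in \[0, 1\].
#' @return a list with elements `msa` (trimmed alignment) and `col_map`, a
#'   data.frame with one row per original column: `old` (original index),
#'   `gap_fraction`, `kept`, and `new` (index in the trimmed alignment, NA
#'   if removed).  Rows left without residues are dropped with a warning.
#' @export
gap_trim <- function(x, max_gap_fraction) {
  stopifnot(inherits(x, "amf_msa"),
            is.numeric(max_gap_fraction), length(max_gap_fraction) == 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  gf <- column_gap_fraction(x)
  kept <- if (max_gap_fraction == 0) gf == 0 else gf < max_gap_fraction
  if (!any(kept))
    stop("alignment fully trimmed at max_gap_fraction = ", max_gap_fraction)
  col_map <- data.frame(old = seq_along(gf), gap_fraction = gf, kept = kept,
                        new = ifelse(kept, cumsum(kept), NA_integer_))
  mat <- unclass(x)[, kept, drop = FALSE]
  allgap <- rowSums(mat != "-") == 0
  if (all(allgap))
    stop("alignment fully trimmed at max_gap_fraction = ", max_gap_fraction)
  if (any(allgap)) {
    warning("dropping row(s) left without residues: ",
            paste(rownames(mat)[allgap], collapse = ", "))
    mat <- mat[!allgap, , drop = FALSE]
  }
  list(msa = msa(mat), col_map = col_map)
}

#' Write a gap-trim report
#'
#' One row per original alignment column: index, gap fraction, kept/removed.
#'
#' @param col_map the `col_map` element returned by [gap_trim()].
#' @param path output TSV path.
#' @export
write_trim_report <- function(col_map, path) {
  out <- data.frame(column = col_map$old,
                    gap_fraction = signif(col_map$gap_fraction, 6),
                    status = ifelse(col_map$kept, "kept", "removed"))
  write_tsv(out, path)
}

#' Columns private to a clade (clade-exclusive insertions)
#'
#' Returns the alignment columns where at least `f_in` of the clade rows
#' carry a residue while every row outside the clade has a gap.  Such
#' columns correspond to insertions unique to the clade and explain
#' unusually long branches.
#'
#' @param x an `amf_msa`.
#' @param clade_ids row ids forming the clade; must be a non-empty proper
#'   subset of the alignment rows.
#' @param f_in minimum fraction of clade rows with a residue.
#' @return integer vector of 1-based column indices.
#' @export
clade_exclusive_columns <- function(x, clade_ids, f_in = 0.5) {
  stopifnot(inherits(x, "amf_msa"))
  unknown <- setdiff(clade_ids, rownames(x))
  if (length(unknown) > 0)
    stop("clade ids not in alignment: ", paste(unknown, collapse = ", "))
  if (length(clade_ids) == 0 || length(clade_ids) == nrow(x))
    stop("clade_ids must be a non-empty proper subset of alignment rows")
  inm <- unclass(x)[rownames(x) %in% clade_ids, , drop = FALSE]
  outm <- unclass(x)[!(rownames(x) %in% clade_ids), , drop = FALSE]
  which(colMeans(inm != "-") >= f_in & colSums(outm != "-") == 0)
}
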