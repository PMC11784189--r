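# Internal file-format helpers shared across modules.  FASTA goes through
# ape's reader/writer; tab-delimited tables through utils.  All TSVs are
# UTF-8, tab-delimited, with a header row.

#' @importFrom utils read.delim write.table
NULL

# Read a (possibly gapped) FASTA file into a named character vector of
# uppercase sequences.  U is mapped to T on load (binary DNA readers drop
# RNA letters, so records are parsed as text).  An empty file (no records)
# returns character(0).
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  hdr <- startsWith(lines, ">")
  if (!any(hdr)) return(stats::setNames(character(0), character(0)))
  grp <- cumsum(hdr)
  keep <- grp >= 1
  ids <- sub("^>\\s*", "", lines[hdr])
  body <- split(lines[keep & !hdr], grp[keep & !hdr])
  seqs <- rep("", length(ids))
  present <- as.integer(names(body))
  seqs[present] <- vapply(body, paste, character(1), collapse = "")
  seqs <- gsub("U", "T", toupper(seqs), fixed = TRUE)
  names(seqs) <- ids
  seqs
}

# Write a named character vector of sequences (gapped or not) as FASTA.
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = NULL, ...)
}

write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# IUPAC nucleotide codes (gap excluded); used to validate ungapped sequences.
IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

is_iupac_dna <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)
  vapply(chars, function(ch) length(ch) > 0L && all(ch %in% IUPAC_DNA), logical(1))
}

# Reverse complement honouring IUPAC ambiguity codes.
revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N", `-` = "-")
  vapply(strsplit(toupper(s), "", fixed = TRUE),
         function(ch) paste(rev(unname(comp[ch])), collapse = ""), character(1))
}
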