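# Reference-set curation: reading, validating, merging the curated 18S
# reference sequences and their four-rank lineages, plus query ASV input.
#
# A reference set is a plain data.frame with one row per reference sequence
# and columns: seq_id, sequence, order, family, genus, species,
# is_type_culture, source_set.  An empty species field means the record is
# identified only to genus; downstream assignment then uses it as
# genus-level evidence only.

REF_TAXONOMY_COLS <- c("seq_id", "order", "family", "genus", "species", "is_type_culture")

validate_reference_set <- function(refs) {
  stopifnot(is.data.frame(refs))
  missing <- setdiff(c(REF_TAXONOMY_COLS, "sequence"), names(refs))
  if (length(missing) > 0)
    stop("reference set is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(refs$seq_id))
    stop("duplicate seq_id in reference set: ",
         paste(unique(refs$seq_id[duplicated(refs$seq_id)]), collapse = ", "))
  bad <- !is_iupac_dna(refs$sequence)
  if (any(bad))
    stop("non-IUPAC or empty sequence for: ", paste(refs$seq_id[bad], collapse = ", "))
  has_sp <- nzchar(refs$species)
  bad_sp <- has_sp & !startsWith(refs$species, paste0(refs$genus, " "))
  if (any(bad_sp))
    stop("species does not begin with genus for: ",
         paste(refs$seq_id[bad_sp], collapse = ", "))
  invisible(refs)
}

#' Load a curated reference sequence set
#'
#' Reads a reference 18S sequence FASTA together with its taxonomy table
#' (tab-delimited with header: seq_id, order, family, genus, species,
#' is_type_culture) and returns a validated reference set.  Every FASTA id
#' must have a taxonomy row and vice versa.  Records duplicated on `seq_id`
#' with identical fields are deduplicated; conflicting duplicates are an
#' error.  Sequences are upcased and U is mapped to T.
#'
#' @param taxonomy_path path to the taxonomy TSV.
#' @param fasta_path path to the reference FASTA.
#' @param source_set label recording which reference study the set came from
#'   (`"set_A"` or `"set_B"`).
#' @return a data.frame with columns seq_id, sequence, order, family, genus,
#'   species, is_type_culture, source_set.
#' @export
load_references <- function(taxonomy_path, fasta_path, source_set = "set_A") {
  source_set <- match.arg(source_set, c("set_A", "set_B"))
  tax <- read_tsv(taxonomy_path)
  missing_cols <- setdiff(REF_TAXONOMY_COLS, names(tax))
  if (length(missing_cols) > 0)
    stop("taxonomy table missing columns: ", paste(missing_cols, collapse = ", "))
  seqs <- read_fasta(fasta_path)
  if (length(seqs) == 0 && nrow(tax) == 0) {
    warning("empty reference set loaded from ", fasta_path)
    out <- data.frame(seq_id = character(0), sequence = character(0),
                      order = character(0), family = character(0),
                      genus = character(0), species = character(0),
                      is_type_culture = logical(0), source_set = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  no_tax <- setdiff(names(seqs), tax$seq_id)
  if (length(no_tax) > 0)
    stop("missing taxonomy row for FASTA id(s): ", paste(no_tax, collapse = ", "))
  no_seq <- setdiff(tax$seq_id, names(seqs))
  if (length(no_seq) > 0)
    stop("missing FASTA record for taxonomy id(s): ", paste(no_seq, collapse = ", "))
  tax$species[is.na(tax$species)] <- ""
  refs <- data.frame(seq_id = tax$seq_id,
                     sequence = unname(seqs[tax$seq_id]),
                     order = tax$order, family = tax$family, genus = tax$genus,
                     species = tax$species,
                     is_type_culture = as.logical(tax$is_type_culture),
                     source_set = source_set, stringsAsFactors = FALSE)
  # deduplicate on seq_id: identical rows collapse, conflicting rows error
  if (anyDuplicated(refs$seq_id)) {
    key_cols <- c("seq_id", "sequence", "order", "family", "genus", "species")
    uniq <- refs[!duplicated(refs[key_cols]), , drop = FALSE]
    if (anyDuplicated(uniq$seq_id))
      stop("conflicting records for duplicated seq_id: ",
           paste(unique(uniq$seq_id[duplicated(uniq$seq_id)]), collapse = ", "))
    refs <- uniq
  }
  rownames(refs) <- NULL
  validate_reference_set(refs)
  message(sprintf("loaded %d reference records (%d species, %d genera) from %s",
                  nrow(refs), length(unique(refs$species[nzchar(refs$species)])),
                  length(unique(refs$genus)), fasta_path))
  refs
}

#' Merge two reference sets
#'
#' Union on `seq_id`.  Records present in both sets must carry identical
#' lineage and sequence; a conflict is an error listing both lineages.
#' Merging is commutative and idempotent on conflict-free inputs.
#'
#' @param set_a,set_b reference sets as returned by [load_references()].
#' @return the merged reference set.
#' @export
merge_reference_sets <- function(set_a, set_b) {
  validate_reference_set(set_a)
  validate_reference_set(set_b)
  shared <- intersect(set_a$seq_id, set_b$seq_id)
  if (length(shared) > 0) {
    a <- set_a[match(shared, set_a$seq_id), , drop = FALSE]
    b <- set_b[match(shared, set_b$seq_id), , drop = FALSE]
    cmp_cols <- c("sequence", "order", "family", "genus", "species")
    conflict <- vapply(seq_along(shared),
                       function(i) !identical(unlist(a[i, cmp_cols]), unlist(b[i, cmp_cols])),
                       logical(1))
    if (any(conflict)) {
      id <- shared[conflict][1]
      stop("lineage conflict for shared seq_id '", id, "': set A has [",
           paste(unlist(a[match(id, shared), cmp_cols[-1]]), collapse = "; "),
           "] but set B has [",
           paste(unlist(b[match(id, shared), cmp_cols[-1]]), collapse = "; "), "]")
    }
  }
  out <- rbind(set_a, set_b[!(set_b$seq_id %in% set_a$seq_id), , drop = FALSE])
  rownames(out) <- NULL
  validate_reference_set(out)
  out
}

#' Write a reference set back to FASTA + taxonomy TSV
#'
#' Inverse of [load_references()]: `load -> write -> load` is the identity on
#' (seq_id, sequence, lineage).
#'
#' @param refs a reference set.
#' @param taxonomy_path,fasta_path output paths.
#' @export
write_references <- function(refs, taxonomy_path, fasta_path) {
  validate_reference_set(refs)
  write_tsv(refs[REF_TAXONOMY_COLS], taxonomy_path)
  write_fasta(stats::setNames(refs$sequence, refs$seq_id), fasta_path)
  invisible(list(taxonomy = taxonomy_path, fasta = fasta_path))
}

#' Load query ASV sequences
#'
#' Reads a FASTA of amplicon sequence variants.  Record order is preserved,
#' sequences are upcased (U mapped to T), and a duplicated ASV id is an
#' error.
#'
#' @param fasta_path path to the query FASTA.
#' @return a data.frame with columns asv_id, sequence.
#' @export
load_queries <- function(fasta_path) {
  seqs <- read_fasta(fasta_path)
  if (anyDuplicated(names(seqs)))
    stop("duplicate asv_id in query FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  bad <- !is_iupac_dna(seqs)
  if (any(bad))
    stop("non-IUPAC or empty query sequence: ", paste(names(seqs)[bad], collapse = ", "))
  data.frame(asv_id = names(seqs), sequence = unname(seqs), stringsAsFactors = FALSE)
}
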