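# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately written from first principles (edge-matrix recursion, per-
# column scans, exhaustive enumeration) and never call the package paths
# they are used to check.

# ---- tiny fixture builders -------------------------------------------------

DUMMY_SEQ <- "ACGTACGTACGTACGT"

# quick reference set: lineage vectors recycled, dummy sequences
ref_df <- function(seq_id, genus, species = paste(genus, "sp01"),
                   family = paste0(genus, "aceae"), order = "Glomerales",
                   is_type_culture = FALSE, source_set = "set_A",
                   sequence = DUMMY_SEQ) {
  data.frame(seq_id = seq_id, sequence = sequence, order = order,
             family = family, genus = genus, species = species,
             is_type_culture = is_type_culture, source_set = source_set,
             stringsAsFactors = FALSE)
}

write_ref_files <- function(refs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  tax <- file.path(dir, "tax.tsv")
  fas <- file.path(dir, "ref.fasta")
  utils::write.table(refs[c("seq_id", "order", "family", "genus", "species",
                            "is_type_culture")],
                     tax, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- as.vector(rbind(paste0(">", refs$seq_id), refs$sequence))
  writeLines(lines, fas)
  list(taxonomy = tax, fasta = fas)
}

write_fasta_file <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

random_alignment <- function(nrow, ncol, gap_prob = 0.15, ids = paste0("s", seq_len(nrow))) {
  mat <- matrix(sample(c("A", "C", "G", "T"), nrow * ncol, replace = TRUE),
                nrow = nrow)
  gaps <- matrix(stats::runif(nrow * ncol) < gap_prob, nrow = nrow)
  mat[gaps] <- "-"
  # keep every row and column with at least one residue
  for (i in seq_len(nrow)) if (all(mat[i, ] == "-")) mat[i, 1] <- "A"
  rownames(mat) <- ids
  msa(mat)
}

# ---- tree oracles (edge-matrix recursion, no ape/phangorn helpers) ---------

# list of tip-label sets, one per node (tips included), indexed by node id
oracle_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sets <- vector("list", ntip + nnode)
  visit <- function(node) {
    if (node <= ntip) {
      sets[[node]] <<- tree$tip.label[node]
    } else {
      for (k in kids[[as.character(node)]]) visit(k)
      sets[[node]] <<- unlist(lapply(kids[[as.character(node)]],
                                     function(k) sets[[k]]))
    }
  }
  visit(ntip + 1L)
  sets
}

oracle_is_monophyletic <- function(tree, tipset) {
  any(vapply(oracle_clades(tree), function(s) setequal(s, tipset), logical(1)))
}

# same consensus semantics, written independently: deepest unanimous rank
oracle_consensus <- function(rows) {
  sp <- rows$species[rows$species != ""]
  if (length(sp) >= 1 && all(sp == sp[1]) && all(rows$genus == rows$genus[1]))
    return(c("species", sp[1]))
  if (all(rows$genus == rows$genus[1])) return(c("genus", rows$genus[1]))
  if (all(rows$family == rows$family[1])) return(c("family", rows$family[1]))
  if (all(rows$order == rows$order[1])) return(c("order", rows$order[1]))
  c("unclassified", "unknown")
}

# smallest clade containing the query and >= 1 reference (clades containing
# a given tip are nested, so "smallest" is unique); support filter applied
# when given
oracle_assign_one <- function(tree, refs, q, min_support = NULL) {
  sets <- oracle_clades(tree)
  ntip <- length(tree$tip.label)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  cand <- which(vapply(sets, function(s)
    (q %in% s) && length(s) > 1 && any(s %in% refs$seq_id), logical(1)))
  if (!is.null(min_support)) {
    keep <- vapply(cand, function(nd) {
      s <- if (nd > ntip) sup[nd - ntip] else NA_real_
      is.na(s) || s >= min_support
    }, logical(1))
    cand <- cand[keep]
  }
  if (length(cand) == 0) return(c("unclassified", "unknown"))
  best <- cand[which.min(vapply(cand, function(nd) length(sets[[nd]]), numeric(1)))]
  oracle_consensus(refs[refs$seq_id %in% sets[[best]], , drop = FALSE])
}

# maximal all-query clades of size >= min_size, as a list of tip-label sets
oracle_novel_clades <- function(tree, ref_ids, min_size = 2) {
  sets <- oracle_clades(tree)
  ntip <- length(tree$tip.label)
  allq <- vapply(sets, function(s) !any(s %in% ref_ids), logical(1))
  parent <- rep(NA_integer_, length(sets))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  idx <- which(allq & vapply(sets, length, numeric(1)) >= min_size &
                 seq_along(sets) > ntip)
  idx <- idx[vapply(idx, function(nd) is.na(parent[nd]) || !allq[parent[nd]],
                    logical(1))]
  lapply(idx, function(nd) sets[[nd]])
}

# ---- per-column and count-table oracles ------------------------------------

oracle_gap_trim_kept <- function(mat, t) {
  kept <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    gf <- sum(mat[, j] == "-") / nrow(mat)
    kept[j] <- if (t == 0) gf == 0 else gf < t
  }
  kept
}

oracle_low_count_removed <- function(counts, max_total) {
  removed <- character(0)
  for (j in seq_len(ncol(counts))) {
    if (sum(counts[, j]) <= max_total) removed <- c(removed, colnames(counts)[j])
  }
  removed
}

# ---- ANOSIM oracles --------------------------------------------------------

oracle_anosim_R <- function(dm, groups) {
  n <- nrow(dm)
  d <- w <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, dm[i, j]); w <- c(w, groups[i] == groups[j])
  }
  r <- rank(d)
  M <- length(d)
  (mean(r[w == 0]) - mean(r[w == 1])) / (M / 2)
}

# exhaustive two-group null: every assignment of n1 positions to group 1
oracle_anosim_exhaustive_p <- function(dm, groups) {
  n <- nrow(dm)
  levs <- unique(groups)
  stopifnot(length(levs) == 2)
  n1 <- sum(groups == levs[1])
  obs <- oracle_anosim_R(dm, groups)
  sets <- utils::combn(n, n1)
  Rs <- apply(sets, 2, function(idx) {
    g <- rep(levs[2], n); g[idx] <- levs[1]
    oracle_anosim_R(dm, g)
  })
  mean(Rs >= obs - 1e-12)
}

# small scaled-down simulation configuration used across tests (the planted
# effects reference genera present in the reduced genus set)
small_cfg <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, n_genera = 6, n_species = 12, n_reference_seqs = 18,
    amplicon_len = 300, variants_min = 1, variants_max = 4,
    reads_per_sample = 1000, replicates = 3,
    genotypes = c("G.890", "M.26"),
    effects = list(
      list(type = "dropout", rank = "genus", taxon = "Rhizophagus",
           treatment = "CM1x"),
      list(type = "enrichment", rank = "genus", taxon = "Sclerocystis",
           treatment = "CM1x", factor = 8),
      list(type = "novel_lineage", n_variants = 4, divergence = 0.08,
           insertion_len = 12, base_share = 0.15),
      list(type = "off_target", n = 3, divergence = 0.3)))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
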