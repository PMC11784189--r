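# Core annotation: assign taxonomy to query ASVs from the smallest
# monophyletic group housing them together with reference sequences, detect
# query-only novel clades, attach long-branch and insertion diagnostics,
# and filter off-target (non-ingroup) queries.

RANKS <- c("species", "genus", "family", "order")

# Consensus lineage over the reference tips inside a housing clade: the
# deepest rank at which all lineages agree.  References with an empty
# species field contribute evidence only at genus and above.  Disagreement
# at order level yields rank = "unclassified", taxon = "unknown".
consensus_rank <- function(ref_rows) {
  sp <- ref_rows$species[nzchar(ref_rows$species)]
  if (length(sp) > 0 && length(unique(sp)) == 1 &&
      length(unique(ref_rows$genus)) == 1)
    return(list(rank = "species", taxon = sp[1]))
  for (rk in c("genus", "family", "order")) {
    v <- ref_rows[[rk]]
    if (length(unique(v)) == 1) return(list(rank = rk, taxon = v[1]))
  }
  list(rank = "unclassified", taxon = "unknown")
}

#' Assign taxonomy to query tips from a rooted tree
#'
#' For each query tip the ancestors are walked rootward starting at the
#' tip's parent; the housing clade is the first ancestor whose descendant
#' tips include at least one reference sequence and, when `min_support` is
#' given, whose support meets it (nodes without a support value pass).  The
#' lineages of all reference tips inside the housing clade are collapsed to
#' the deepest unanimous rank (species > genus > family > order); full
#' disagreement yields `rank = "unclassified"`, `taxon = "unknown"`.  The
#' result is deterministic given the tree and taxonomy.
#'
#' @param tree a rooted `phylo` whose tips are reference seq_ids and query
#'   ASV ids.
#' @param references a reference set (see [load_references()]).
#' @param min_support optional minimum node support for a housing clade.
#' @param query_ids optional explicit query tip labels; defaults to all
#'   tips absent from the reference taxonomy.  A query id present in the
#'   reference taxonomy is an error.
#' @return a data.frame with one row per query tip (in tree tip order):
#'   asv_id, rank, taxon, housing_clade_support, novel_clade_id (NA here;
#'   see [detect_novel_clades()]), long_branch, exclusive_insertion_cols,
#'   and housing_node (internal node number, used by
#'   [filter_off_target()]).
#' @export
assign_taxonomy <- function(tree, references, min_support = NULL, query_ids = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted (see root_on_outgroup)")
  validate_reference_set(references)
  ref_tips <- intersect(tree$tip.label, references$seq_id)
  if (length(ref_tips) == 0) stop("no reference tips present in the tree")
  if (is.null(query_ids)) {
    query_ids <- setdiff(tree$tip.label, references$seq_id)
  } else {
    clash <- intersect(query_ids, references$seq_id)
    if (length(clash) > 0)
      stop("query tip(s) listed in the reference taxonomy: ",
           paste(clash, collapse = ", "))
    unknown <- setdiff(query_ids, tree$tip.label)
    if (length(unknown) > 0)
      stop("query tip(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  query_ids <- tree$tip.label[tree$tip.label %in% query_ids]  # tree tip order
  ntip <- ape::Ntip(tree)
  desc <- descendant_tips(tree)
  sup <- node_support(tree)
  is_ref_tip <- tree$tip.label %in% ref_tips
  n_ref_below <- vapply(desc, function(tt) sum(is_ref_tip[tt]), integer(1))
  sup_of <- function(node) sup[node - ntip]
  sup_ok <- function(node) {
    if (is.null(min_support)) return(TRUE)
    s <- sup_of(node)
    is.na(s) || s >= min_support
  }
  out <- vector("list", length(query_ids))
  for (k in seq_along(query_ids)) {
    q <- match(query_ids[k], tree$tip.label)
    anc <- phangorn::Ancestors(tree, q, type = "all")  # parent first, root last
    housing <- NA_integer_
    for (node in anc) {
      if (n_ref_below[node] >= 1 && sup_ok(node)) { housing <- node; break }
    }
    if (is.na(housing)) {
      # only reachable with min_support filtering every ref-containing
      # ancestor including the root
      out[[k]] <- data.frame(asv_id = query_ids[k], rank = "unclassified",
                             taxon = "unknown", housing_clade_support = NA_real_,
                             housing_node = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    in_clade <- tree$tip.label[desc[[housing]]]
    ref_rows <- references[references$seq_id %in% in_clade, , drop = FALSE]
    cons <- consensus_rank(ref_rows)
    out[[k]] <- data.frame(asv_id = query_ids[k], rank = cons$rank,
                           taxon = cons$taxon,
                           housing_clade_support = sup_of(housing),
                           housing_node = housing, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(asv_id = character(0), rank = character(0),
                      taxon = character(0), housing_clade_support = numeric(0),
                      housing_node = integer(0), stringsAsFactors = FALSE)
  res$novel_clade_id <- NA_character_
  res$long_branch <- FALSE
  res$exclusive_insertion_cols <- 0L
  rownames(res) <- NULL
  res[c("asv_id", "rank", "taxon", "housing_clade_support", "novel_clade_id",
        "long_branch", "exclusive_insertion_cols", "housing_node")]
}

#' Detect query-only (novel) clades
#'
#' Returns the maximal clades whose descendant tips are all queries, of
#' size at least `min_novel_size`, optionally restricted to clades whose
#' support meets `min_support` (nodes without a support value pass).
#' Clades are reported in root-to-tip order and labelled NC1, NC2, ...
#'
#' @param tree a rooted `phylo`.
#' @param reference_ids tip labels that are reference sequences (tips not
#'   listed are treated as queries).
#' @inheritParams assign_taxonomy
#' @param min_novel_size minimum clade size.
#' @return a data.frame with columns clade_id, node, size, support, and a
#'   list-column `members` of ASV ids.
#' @export
detect_novel_clades <- function(tree, reference_ids, min_novel_size = 2,
                                min_support = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- ape::Ntip(tree)
  desc <- descendant_tips(tree)
  sup <- node_support(tree)
  is_query <- !(tree$tip.label %in% reference_ids)
  all_query <- vapply(desc, function(tt) all(is_query[tt]), logical(1))
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  cand <- nodes[all_query[nodes] &
                  vapply(nodes, function(n) length(desc[[n]]) >= min_novel_size, logical(1))]
  # maximal: parent is not itself an all-query clade (root has no parent)
  maximal <- cand[vapply(cand, function(n) is.na(parent[n]) || !all_query[parent[n]],
                         logical(1))]
  if (!is.null(min_support)) {
    s <- sup[maximal - ntip]
    maximal <- maximal[is.na(s) | s >= min_support]
  }
  if (length(maximal) == 0)
    return(data.frame(clade_id = character(0), node = integer(0),
                      size = integer(0), support = numeric(0),
                      members = I(list()), stringsAsFactors = FALSE))
  depth <- vapply(maximal, function(n) length(phangorn::Ancestors(tree, n, "all")),
                  integer(1))
  maximal <- maximal[order(depth, maximal)]
  data.frame(clade_id = paste0("NC", seq_along(maximal)), node = maximal,
             size = vapply(maximal, function(n) length(desc[[n]]), integer(1)),
             support = sup[maximal - ntip],
             members = I(lapply(maximal, function(n) tree$tip.label[desc[[n]]])),
             stringsAsFactors = FALSE)
}

#' Attach novel-clade membership to an assignment table
#'
#' @param assignments table from [assign_taxonomy()].
#' @param novel_clades table from [detect_novel_clades()].
#' @return the assignment table with `novel_clade_id` filled in for members
#'   of each novel clade.
#' @export
annotate_novel_clades <- function(assignments, novel_clades) {
  for (i in seq_len(nrow(novel_clades))) {
    hit <- assignments$asv_id %in% novel_clades$members[[i]]
    assignments$novel_clade_id[hit] <- novel_clades$clade_id[i]
  }
  assignments
}

#' Attach long-branch and clade-exclusive insertion diagnostics
#'
#' Sets `long_branch` from [long_branch_tips()] and, for each novel clade
#' present in the assignment table, `exclusive_insertion_cols` from
#' [clade_exclusive_columns()] applied to the clade members.
#'
#' @param assignments table from [assign_taxonomy()] (with
#'   `novel_clade_id` filled in, see [annotate_novel_clades()]).
#' @param tree the rooted `phylo` used for assignment.
#' @param x the `amf_msa` underlying the tree; its rows must be exactly the
#'   tree tips.
#' @param factor long-branch multiplier (see [long_branch_tips()]).
#' @param f_in clade-residue fraction (see [clade_exclusive_columns()]).
#' @return the enriched assignment table.
#' @export
annotate_diagnostics <- function(assignments, tree, x, factor = 5, f_in = 0.5) {
  stopifnot(inherits(tree, "phylo"), inherits(x, "amf_msa"))
  sym <- c(setdiff(tree$tip.label, rownames(x)), setdiff(rownames(x), tree$tip.label))
  if (length(sym) > 0)
    stop("tree tips and alignment rows differ: ", paste(sym, collapse = ", "))
  flagged <- long_branch_tips(tree, factor = factor, scope = "tips")
  assignments$long_branch <- assignments$asv_id %in% flagged
  assignments$exclusive_insertion_cols <- 0L
  for (nc in unique(stats::na.omit(assignments$novel_clade_id))) {
    members <- assignments$asv_id[!is.na(assignments$novel_clade_id) &
                                    assignments$novel_clade_id == nc]
    cols <- clade_exclusive_columns(x, members, f_in = f_in)
    assignments$exclusive_insertion_cols[assignments$asv_id %in% members] <-
      length(cols)
  }
  assignments
}

#' Split assignments into on-target and off-target queries
#'
#' Queries whose housing clade lies on the outgroup side of the root, or
#' whose housing clade is the root itself (the query attaches to the root
#' edge), are removed as non-target (non-Glomeromycotan in the study
#' design); all other queries are kept.
#'
#' @param assignments table from [assign_taxonomy()].
#' @param tree the rooted `phylo` used for assignment.
#' @param outgroup_ids tip labels of the outgroup.
#' @return a list with data.frames `kept` and `removed`.
#' @export
filter_off_target <- function(assignments, tree, outgroup_ids) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  unknown <- setdiff(outgroup_ids, tree$tip.label)
  if (length(unknown) > 0)
    stop("outgroup tips not in tree: ", paste(unknown, collapse = ", "))
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  desc <- descendant_tips(tree)
  # ingroup references are the tree tips that are neither queries nor
  # outgroup; the outgroup side of the root holds outgroup tips and no
  # ingroup reference
  ingroup_refs <- setdiff(tree$tip.label, c(assignments$asv_id, outgroup_ids))
  out_side <- kids[vapply(kids, function(k) {
    tt <- tree$tip.label[desc[[k]]]
    any(tt %in% outgroup_ids) && !any(tt %in% ingroup_refs)
  }, logical(1))]
  out_tips <- unique(unlist(lapply(out_side, function(k) tree$tip.label[desc[[k]]])))
  removed <- assignments$asv_id %in% out_tips |
    (!is.na(assignments$housing_node) & assignments$housing_node == root)
  list(kept = assignments[!removed, , drop = FALSE],
       removed = assignments[removed, , drop = FALSE])
}

#' Write an assignment table
#'
#' One row per query tip: asv_id, rank, taxon, housing_clade_support,
#' novel_clade_id, long_branch, exclusive_insertion_cols.
#'
#' @param assignments an assignment table.
#' @param path output TSV path.
#' @export
write_assignments <- function(assignments, path) {
  cols <- c("asv_id", "rank", "taxon", "housing_clade_support", "novel_clade_id",
            "long_branch", "exclusive_insertion_cols")
  write_tsv(assignments[cols], path)
}
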