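# Tree I/O and tree algorithms on ape "phylo" objects: newick parsing with
# bootstrap-support node labels, Jukes-Cantor distances with a
# neighbor-joining fallback builder for desk-scale tests, outgroup rooting,
# monophyly queries, and long-branch flagging.

#' Parse a newick tree
#'
#' Wraps [ape::read.tree()].  Numeric internal-node labels are interpreted
#' as bootstrap support values; values that all lie in \[0, 1\] are
#' auto-scaled to \[0, 100\] with a warning (newick dialects differ).
#' Duplicate tip labels are an error.
#'
#' @param x newick text, or the path of a file containing it.
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(x) {
  tr <- tryCatch(
    if (length(x) == 1 && !grepl("(", x, fixed = TRUE) && file.exists(x))
      ape::read.tree(file = x)
    else ape::read.tree(text = x),
    error = function(e) stop("newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("newick parse error: malformed tree text")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  sup <- node_support(tr)
  if (any(!is.na(sup)) && all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 1) &&
      any(sup[!is.na(sup)] > 0)) {
    warning("node support values in [0, 1]; rescaling to [0, 100]")
    lab <- tr$node.label
    num <- suppressWarnings(as.numeric(lab))
    lab[!is.na(num)] <- format(num[!is.na(num)] * 100, trim = TRUE)
    tr$node.label <- lab
  }
  tr
}

#' @rdname parse_newick
#' @param tree a `phylo` object.
#' @param path optional file path; when NULL the newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = path); invisible(path) }
}

#' Numeric node support values
#'
#' @param tree a `phylo` object.
#' @return numeric vector of length `tree$Nnode` (NA where the label is
#'   absent or non-numeric), indexed by internal node number minus the
#'   number of tips.
#' @export
node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  length(sup) <- tree$Nnode
  sup
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' For each pair of rows, the mismatch proportion p is computed over the
#' columns where both rows carry a residue, and corrected as
#' d = -(3/4) log(1 - (4/3) p).  Saturated pairs (p >= 0.75) are set to
#' `max_distance` with a warning.  A pair with no overlapping residue
#' columns is an error.
#'
#' @param x an `amf_msa`.
#' @param max_distance ceiling substituted for saturated pairs.
#' @return a symmetric numeric matrix with zero diagonal, dimnames = row
#'   ids.
#' @export
jc_distance <- function(x, max_distance = 5) {
  stopifnot(inherits(x, "amf_msa"), nrow(x) >= 2)
  mat <- unclass(x)
  res <- mat != "-"
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  saturated <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- res[i, ] & res[j, ]
      if (!any(both))
        stop("no overlapping residue columns for pair ",
             rownames(mat)[i], " / ", rownames(mat)[j])
      p <- mean(mat[i, both] != mat[j, both])
      if (p >= 0.75) {
        d[i, j] <- d[j, i] <- max_distance
        saturated <- c(saturated, paste(rownames(mat)[i], rownames(mat)[j], sep = "/"))
      } else {
        d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
      }
    }
  }
  if (length(saturated) > 0)
    warning("saturated pair(s) set to ceiling ", max_distance, ": ",
            paste(saturated, collapse = ", "))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining via [ape::nj()]; on additive distance matrices
#' the generating topology is recovered exactly.  Intended as a desk-scale
#' fallback when no externally inferred tree is supplied.
#'
#' @param dm symmetric numeric matrix with dimnames (or a `dist`).
#' @return an unrooted `phylo`.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  ape::nj(stats::as.dist(dm))
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge separating the outgroup tips from the
#' ingroup.  If the outgroup is not monophyletic in the unrooted tree, a
#' warning is issued and the root is placed at the smallest clade enclosing
#' all outgroup tips.
#'
#' @param tree a `phylo`.
#' @param outgroup_ids tip labels of the outgroup; non-empty proper subset
#'   of the tips.
#' @return a rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup_ids) {
  stopifnot(inherits(tree, "phylo"))
  outgroup_ids <- unique(outgroup_ids)
  unknown <- setdiff(outgroup_ids, tree$tip.label)
  if (length(unknown) > 0)
    stop("outgroup tips not in tree: ", paste(unknown, collapse = ", "))
  if (length(outgroup_ids) == 0 || length(outgroup_ids) == length(tree$tip.label))
    stop("outgroup must be a non-empty proper subset of the tips")
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_ids, resolve.root = TRUE, edgelabel = TRUE),
    error = function(e) NULL)
  if (is.null(rooted)) {
    warning("outgroup is not monophyletic in the unrooted tree; ",
            "rooting at its smallest enclosing clade")
    un <- ape::unroot(tree)
    m <- ape::getMRCA(un, outgroup_ids)
    rooted <- if (m == ape::Ntip(un) + 1L)
      # the enclosing clade is the whole tree: fall back to the first
      # outgroup tip's edge
      ape::root(un, outgroup = outgroup_ids[1], resolve.root = TRUE,
                edgelabel = TRUE)
    else
      ape::root(un, node = m, resolve.root = TRUE, edgelabel = TRUE)
  }
  rooted
}

# tip numbers (1..Ntip) descending from each node, as a list indexed by node
# number; thin wrapper kept internal so callers share one phangorn call.
descendant_tips <- function(tree) {
  phangorn::Descendants(tree, seq_len(ape::Ntip(tree) + tree$Nnode), type = "tips")
}

#' Monophyly test and MRCA lookup
#'
#' `is_monophyletic` is TRUE iff the tip descendants of the MRCA of `tips`
#' equal `tips` exactly (a singleton tip is its own clade).  Multifurcations
#' are honoured as-is.
#'
#' @param tree a rooted `phylo`.
#' @param tips character vector of tip labels.
#' @return logical scalar / internal node (or tip) number.
#' @export
is_monophyletic <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) > 0)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "))
  if (length(tips) == 1) return(TRUE)
  m <- mrca_node(tree, tips)
  desc <- tree$tip.label[phangorn::Descendants(tree, m, type = "tips")[[1]]]
  setequal(desc, tips)
}

#' @rdname is_monophyletic
#' @export
mrca_node <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0)
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "))
  if (length(tips) == 1) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Flag unusually long branches
#'
#' Flags tips (or internal clade root edges) whose branch length exceeds
#' `factor` times the median tip branch length.  Long terminal branches in
#' AMF 18S trees are diagnostic of clade-exclusive insertions that fail to
#' align.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param factor multiplier over the median tip branch length.
#' @param scope `"tips"` flags individual tips; `"clades"` flags internal
#'   edges and returns all tip labels under each flagged edge.
#' @return character vector of flagged tip labels (empty, with a warning,
#'   when all branch lengths are zero).
#' @export
long_branch_tips <- function(tree, factor = 5, scope = c("tips", "clades")) {
  scope <- match.arg(scope)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; nothing to flag")
    return(character(0))
  }
  ntip <- ape::Ntip(tree)
  is_tip_edge <- tree$edge[, 2] <= ntip
  tip_lengths <- tree$edge.length[is_tip_edge]
  med <- stats::median(tip_lengths)
  cutoff <- factor * med
  if (scope == "tips") {
    flagged <- tree$edge[is_tip_edge, 2][tip_lengths > cutoff]
    return(tree$tip.label[flagged])
  }
  internal <- which(!is_tip_edge & tree$edge.length > cutoff)
  if (length(internal) == 0) return(character(0))
  desc <- descendant_tips(tree)
  sort(unique(tree$tip.label[unlist(desc[tree$edge[internal, 2]])]))
}
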