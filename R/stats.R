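# Community comparison: Bray-Curtis dissimilarity and one-way ANOSIM with
# a permutation null.  Bray-Curtis goes through vegan; the ANOSIM statistic
# and its permutation (or exhaustive) null are computed here so that the
# seed, the add-one p-value rule, and exhaustive enumeration on small
# designs are under explicit control.

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) between all pairs of rows.
#'
#' @param ab a nonnegative matrix (samples x ASVs) with at least 2 rows.
#' @return a symmetric matrix in \[0, 1\] with zero diagonal.
#' @export
bray_curtis <- function(ab) {
  stopifnot(is.matrix(ab), nrow(ab) >= 2)
  if (any(ab < 0)) stop("Bray-Curtis requires nonnegative values")
  zero <- rowSums(ab) == 0
  if (sum(zero) >= 2)
    stop("all-zero sample pair(s): ", paste(rownames(ab)[zero], collapse = ", "))
  m <- as.matrix(vegan::vegdist(ab, method = "bray"))
  diag(m) <- 0
  m
}

# All distinct assignments of a label multiset to positions, as a list of
# character vectors.  Used for exhaustive ANOSIM nulls on small designs.
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(pool) {
    if (length(pool) == 0) return(list(character(0)))
    out <- list()
    for (l in unique(pool)) {
      rest <- pool[-match(l, pool)]
      out <- c(out, lapply(rec(rest), function(p) c(l, p)))
    }
    out
  }
  rec(sort(labels))
}

anosim_R <- function(ranks, within, M) {
  (mean(ranks[!within]) - mean(ranks[within])) / (M / 2)
}

#' One-way analysis of similarities (ANOSIM)
#'
#' Ranks all n(n-1)/2 pairwise dissimilarities (ties receive average ranks)
#' and computes R = (mean between-group rank - mean within-group rank) /
#' (M/2).  The null distribution is built by permuting the group labels;
#' the one-sided p-value follows the add-one rule
#' p = (1 + #\{permuted R >= observed R\}) / (1 + n_permutations), so p is
#' never 0.  With `exhaustive = TRUE` all distinct label assignments are
#' enumerated instead and p is the exact proportion (the identity
#' assignment included) with R >= observed.
#'
#' @param dm symmetric dissimilarity matrix (or `dist`).
#' @param groups group label per sample (same order as `dm` rows); at least
#'   2 groups, each of size >= 2.
#' @param n_permutations number of label permutations (ignored when
#'   `exhaustive = TRUE`).
#' @param seed integer seed for the permutation stream.
#' @param exhaustive enumerate all distinct relabelings (small designs
#'   only).
#' @return an object of class `amf_anosim`: list with R, p_value,
#'   n_permutations, seed, group_sizes, exhaustive.
#' @export
anosim <- function(dm, groups, n_permutations = 9999, seed = NULL,
                   exhaustive = FALSE) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("at least 2 groups required")
  if (any(sizes < 2)) stop("every group must have at least 2 samples")
  if (!exhaustive && (!is.numeric(n_permutations) || n_permutations < 1))
    stop("n_permutations must be >= 1")
  pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
  pj_ <- unlist(lapply(2:n, function(j) seq(j, n)))
  d <- dm[cbind(pj_, pi_)]
  M <- length(d)
  ranks <- rank(d)
  within_obs <- groups[pi_] == groups[pj_]
  R_obs <- anosim_R(ranks, within_obs, M)
  eps <- 1e-12
  if (exhaustive) {
    perms <- multiset_permutations(groups)
    Rs <- vapply(perms, function(g) anosim_R(ranks, g[pi_] == g[pj_], M), numeric(1))
    p <- mean(Rs >= R_obs - eps)
    n_perm <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    B <- as.integer(n_permutations)
    labmat <- replicate(B, sample(groups))
    eq <- labmat[pi_, , drop = FALSE] == labmat[pj_, , drop = FALSE]
    nW <- colSums(eq)
    sumW <- colSums(ranks * eq)
    meanW <- sumW / nW
    meanB <- (sum(ranks) - sumW) / (M - nW)
    Rs <- (meanB - meanW) / (M / 2)
    p <- (1 + sum(Rs >= R_obs - eps)) / (1 + B)
    n_perm <- B
  }
  structure(list(R = R_obs, p_value = p, n_permutations = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 group_sizes = as.integer(sizes), exhaustive = exhaustive),
            class = "amf_anosim")
}

#' @export
print.amf_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s%d permutations; groups: %s)\n",
              x$R, x$p_value, if (x$exhaustive) "exhaustive, " else "",
              x$n_permutations, paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Pairwise one-way ANOSIM between group levels
#'
#' Runs [anosim()] on every pair of group levels.  P-values are reported
#' raw; multiple-testing correction is left to the caller.
#'
#' @inheritParams anosim
#' @return a data.frame with columns group1, group2, R, p_value, n1, n2.
#' @export
pairwise_anosim <- function(dm, groups, n_permutations = 9999, seed = NULL) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  groups <- as.character(groups)
  levs <- unique(groups)
  combos <- utils::combn(levs, 2)
  out <- lapply(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    idx <- groups %in% c(g1, g2)
    res <- anosim(dm[idx, idx, drop = FALSE], groups[idx],
                  n_permutations = n_permutations,
                  seed = if (is.null(seed)) NULL else seed + k)
    data.frame(group1 = g1, group2 = g2, R = res$R, p_value = res$p_value,
               n1 = sum(groups == g1), n2 = sum(groups == g2))
  })
  do.call(rbind, out)
}

#' Write an ANOSIM result as JSON
#'
#' @param x an `amf_anosim`.
#' @param path output path.
#' @export
write_anosim <- function(x, path) {
  jsonlite::write_json(list(R = x$R, p_value = x$p_value,
                            n_permutations = x$n_permutations, seed = x$seed,
                            group_sizes = x$group_sizes),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
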