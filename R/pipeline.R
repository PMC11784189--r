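# End-to-end orchestration: load (or simulate) -> optional window/gap trim
# -> tree (load or NJ fallback) -> root -> assign -> filter -> abundance ->
# clade aggregation -> ANOSIM, with every intermediate written as a plain
# file and a run manifest recording inputs, seed and checksums.

#' Run the full analysis pipeline
#'
#' Stages run in order: load references and queries (or simulate a dataset
#' when `simulate = TRUE`), optionally trim the alignment to the primer
#' window and by gap stringency, obtain a tree (the supplied one, or a
#' neighbor-joining fallback from Jukes-Cantor distances), root it on the
#' outgroup, assign taxonomy, detect novel clades, attach diagnostics,
#' remove off-target queries and low-count ASVs, compute relative
#' abundances, replicate means and clade-level profiles, and compare
#' treatments by Bray-Curtis ANOSIM.  Each stage's output is written to
#' `outdir`; any stage error aborts with the stage name.
#'
#' @param outdir output directory.
#' @param simulate if TRUE, generate the inputs with the synthetic-data
#'   module using `sim` (everything else is read from `indir`).
#' @param sim an [sim_config()] (used when `simulate = TRUE`).
#' @param indir input directory laid out as written by [emit_dataset()]
#'   (used when `simulate = FALSE`).
#' @param use_nj build the tree with the NJ fallback instead of reading
#'   `tree.nwk`.
#' @param trim_window trim the alignment to the AML1/AML2 primer window
#'   before distance/tree computation.
#' @param max_gap_fraction optional gap-trim stringency (default: no
#'   post-alignment trimming, the setting under which tree support is
#'   typically best).
#' @param min_support optional support threshold for housing clades.
#' @param max_total low-count filter threshold (singletons/doubletons).
#' @param long_branch_factor multiplier for long-branch flagging.
#' @param anosim_groups metadata column used as ANOSIM grouping
#'   (`"treatment"` or `"genotype"`).
#' @param n_permutations,seed ANOSIM permutation settings.
#' @return (invisibly) a list with the main in-memory results and the run
#'   manifest.
#' @export
run_pipeline <- function(outdir,
                         simulate = FALSE, sim = sim_config(), indir = NULL,
                         use_nj = FALSE, trim_window = FALSE,
                         max_gap_fraction = NULL, min_support = NULL,
                         max_total = 2, long_branch_factor = 5,
                         anosim_groups = c("treatment", "genotype"),
                         n_permutations = 999, seed = 1L) {
  anosim_groups <- match.arg(anosim_groups)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_msg <- function(...) message(sprintf(...))

  inputs <- stage("load", {
    if (simulate) {
      world <- simulate_reference_world(sim)
      comm <- simulate_communities(sim, world)
      emit_dataset(world, comm, file.path(outdir, "simulated_input"))
      list(refs = world$references, msa = comm$msa, tree = comm$tree,
           counts = comm$counts, meta = comm$meta,
           outgroup = comm$ground_truth$outgroup_tips)
    } else {
      if (is.null(indir)) stop("indir required when simulate = FALSE")
      ds <- load_dataset(indir)
      list(refs = ds$references, msa = ds$msa, tree = ds$tree,
           counts = ds$counts, meta = ds$meta,
           outgroup = ds$manifest$outgroup_tips)
    }
  })
  aln <- inputs$msa
  if (trim_window) {
    aln <- stage("trim_window", {
      w <- locate_primer_window(aln)
      log_msg("primer window: columns %d-%d", w[1], w[2])
      trim_to_window(aln, w)
    })
  }
  if (!is.null(max_gap_fraction)) {
    aln <- stage("gap_trim", {
      gt <- gap_trim(aln, max_gap_fraction)
      write_trim_report(gt$col_map, file.path(outdir, "trim_report.tsv"))
      log_msg("gap trim at %g: %d/%d columns kept", max_gap_fraction,
              sum(gt$col_map$kept), nrow(gt$col_map))
      gt$msa
    })
    write_msa(aln, file.path(outdir, "alignment_trimmed.fasta"))
  }
  tree <- stage("tree", {
    if (use_nj) nj_tree(jc_distance(aln)) else inputs$tree
  })
  if (is.null(tree)) stop("pipeline stage 'tree' failed: no tree supplied and use_nj = FALSE")
  tree <- stage("root", root_on_outgroup(tree, inputs$outgroup))
  write_newick(tree, file.path(outdir, "tree_rooted.nwk"))

  assignments <- stage("assign", {
    a <- assign_taxonomy(tree, inputs$refs, min_support = min_support)
    nc <- detect_novel_clades(tree, inputs$refs$seq_id,
                              min_support = min_support)
    a <- annotate_novel_clades(a, nc)
    if (setequal(rownames(aln), tree$tip.label))
      a <- annotate_diagnostics(a, tree, aln, factor = long_branch_factor)
    log_msg("assigned %d queries (%d novel-clade members)", nrow(a),
            sum(!is.na(a$novel_clade_id)))
    a
  })
  write_assignments(assignments, file.path(outdir, "assignments.tsv"))

  community <- stage("filter", {
    split <- filter_off_target(assignments, tree, inputs$outgroup)
    log_msg("off-target filter: %d kept, %d removed", nrow(split$kept),
            nrow(split$removed))
    counts <- inputs$counts
    off_in_table <- intersect(split$removed$asv_id, colnames(counts))
    if (length(off_in_table) > 0) counts <- drop_asvs(counts, off_in_table)
    lc <- filter_low_count(counts, max_total = max_total)
    log_msg("low-count filter (total <= %d): removed %d ASVs", max_total,
            length(lc$removed))
    list(counts = lc$counts, kept = split$kept, removed_off = split$removed,
         removed_low = lc$removed)
  })
  write_count_table(community$counts, file.path(outdir, "counts_filtered.tsv"))

  ab <- stage("abundance", relative_abundance(community$counts))
  write_count_table(ab, file.path(outdir, "relative_abundance.tsv"))
  means <- stage("replicate_mean", replicate_mean(ab, inputs$meta))
  # heatmap layout: ASVs as rows, groups as columns
  write_tsv(data.frame(asv_id = colnames(means), t(means), check.names = FALSE),
            file.path(outdir, "group_mean_abundance.tsv"))
  clades <- stage("aggregate", {
    keep_assign <- assignments[assignments$asv_id %in% colnames(ab), , drop = FALSE]
    aggregate_by_clade(ab, keep_assign)
  })
  write_count_table(clades, file.path(outdir, "clade_abundance.tsv"))

  anosim_res <- stage("anosim", {
    m <- inputs$meta[match(rownames(ab), inputs$meta$sample_id), , drop = FALSE]
    groups <- m[[anosim_groups]]
    if (length(unique(groups)) < 2 || any(table(groups) < 2)) {
      log_msg("ANOSIM skipped: grouping '%s' has too few groups/replicates",
              anosim_groups)
      NULL
    } else {
      res <- anosim(bray_curtis(ab), groups, n_permutations = n_permutations,
                    seed = seed)
      write_anosim(res, file.path(outdir, "anosim.json"))
      res
    }
  })

  manifest <- stage("manifest", {
    outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    outputs <- outputs[!grepl("run_manifest.json$", outputs)]
    man <- list(package_version = as.character(utils::packageVersion("amfphylo")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed, simulate = simulate,
                parameters = list(trim_window = trim_window,
                                  max_gap_fraction = max_gap_fraction,
                                  min_support = min_support,
                                  max_total = max_total,
                                  long_branch_factor = long_branch_factor,
                                  anosim_groups = anosim_groups,
                                  n_permutations = n_permutations),
                checksums = as.list(tools::md5sum(outputs)))
    jsonlite::write_json(man, file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })
  invisible(list(assignments = assignments, counts = community$counts,
                 abundance = ab, group_means = means, clades = clades,
                 anosim = anosim_res, manifest = manifest))
}
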