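# Monophyly-based taxonomy assignment, novel-clade detection, diagnostics
# and off-target filtering.

fcor_refs <- function() {
  rbind(ref_df("Fcor_ref1", "Funneliformis", "Funneliformis coronatus"),
        ref_df("Fcor_ref2", "Funneliformis", "Funneliformis coronatus"))
}

test_that("ASVs sharing a monophyletic group with one species get species rank", {
  tr <- parse_newick(paste0("((ASV177:1,(ASV178:1,Fcor_ref1:1):1):1,",
                            "(ASV179:1,(ASV166:1,Fcor_ref2:1):1):1);"))
  a <- assign_taxonomy(tr, fcor_refs())
  expect_setequal(a$asv_id, c("ASV177", "ASV178", "ASV179", "ASV166"))
  expect_true(all(a$rank == "species"))
  expect_true(all(a$taxon == "Funneliformis coronatus"))
})

test_that("an ASV falling between species of one genus gets genus rank", {
  refs <- rbind(ref_df("Rirr_ref", "Rhizophagus", "Rhizophagus irregularis"),
                ref_df("Rfas_ref", "Rhizophagus", "Rhizophagus fasciculatus"))
  # the smallest clade housing ASV174 with references contains two
  # different Rhizophagus species, so the unanimous rank is the genus
  tr <- parse_newick("((Rirr_ref:1,Rfas_ref:1):1,ASV174:2);")
  a <- assign_taxonomy(tr, refs)
  expect_equal(a$rank, "genus")
  expect_equal(a$taxon, "Rhizophagus")
})

test_that("a query sister to a single reference takes its species", {
  refs <- ref_df("ref1", "Glomus", "Glomus clarum")
  tr <- parse_newick("((q1:1,ref1:1):1,q2:3);")
  a <- assign_taxonomy(tr, refs)
  expect_equal(a$rank[a$asv_id == "q1"], "species")
  expect_equal(a$taxon[a$asv_id == "q1"], "Glomus clarum")
})

test_that("references identified only to genus contribute genus-level evidence", {
  refs <- rbind(ref_df("r_sp", "Rhizophagus", "Rhizophagus irregularis"),
                ref_df("r_genus", "Rhizophagus", species = ""))
  tr <- parse_newick("((q1:1,r_genus:1):1,r_sp:2);")
  a <- assign_taxonomy(tr, refs)
  expect_equal(a$rank, "genus")
  expect_equal(a$taxon, "Rhizophagus")
})

test_that("lineage disagreement at order level yields unclassified/unknown", {
  refs <- rbind(ref_df("r1", "Glomus", order = "Glomerales"),
                ref_df("r2", "Ambispora", family = "Ambisporaceae",
                       order = "Archaeosporales"))
  tr <- parse_newick("((q1:1,r1:1,r2:1):1,(r1b:1,r2b:1):1);")
  refs2 <- rbind(refs, ref_df("r1b", "Glomus"), ref_df("r2b", "Ambispora",
                 family = "Ambisporaceae", order = "Archaeosporales"))
  a <- assign_taxonomy(tr, refs2)
  expect_equal(a$rank, "unclassified")
  expect_equal(a$taxon, "unknown")
})

test_that("min_support skips weak housing clades and walks rootward", {
  refs <- rbind(ref_df("r1", "Glomus", "Glomus clarum"),
                ref_df("r2", "Glomus", "Glomus monosporum"))
  tr <- parse_newick("((q1:1,r1:1)40:1,r2:2)95;")
  a_none <- assign_taxonomy(tr, refs)
  expect_equal(a_none$rank, "species")
  a_sup <- assign_taxonomy(tr, refs, min_support = 70)
  expect_equal(a_sup$rank, "genus")       # falls through to the root clade
  expect_equal(a_sup$housing_clade_support, 95)
})

test_that("assign_taxonomy equals the brute-force clade-enumeration oracle", {
  set.seed(31)
  genera <- data.frame(genus = c("Glomus", "Rhizophagus", "Ambispora"),
                       family = c("Glomeraceae", "Glomeraceae", "Ambisporaceae"),
                       order = c("Glomerales", "Glomerales", "Archaeosporales"))
  for (rep in 1:150) {
    ntip <- sample(5:25, 1)
    n_ref <- sample(2:max(2, ntip - 2), 1)
    tree <- ape::root(ape::rtree(ntip), 1, resolve.root = TRUE)
    tree$node.label <- as.character(sample(30:100, tree$Nnode, replace = TRUE))
    ref_ids <- sample(tree$tip.label, n_ref)
    gi <- sample(nrow(genera), n_ref, replace = TRUE)
    sp <- paste(genera$genus[gi],
                sample(c("sp01", "sp02", ""), n_ref, replace = TRUE))
    sp <- ifelse(grepl(" $", sp), "", sp)
    refs <- data.frame(seq_id = ref_ids, sequence = DUMMY_SEQ,
                       order = genera$order[gi], family = genera$family[gi],
                       genus = genera$genus[gi], species = sp,
                       is_type_culture = FALSE, source_set = "set_A",
                       stringsAsFactors = FALSE)
    ms <- sample(list(NULL, 60), 1)[[1]]
    a <- assign_taxonomy(tree, refs, min_support = ms)
    for (i in seq_len(nrow(a))) {
      expected <- oracle_assign_one(tree, refs, a$asv_id[i], min_support = ms)
      expect_identical(unname(c(a$rank[i], a$taxon[i])), unname(expected),
                       label = paste("tree rep", rep, "query", a$asv_id[i]))
    }
  }
})

test_that("assignment tables are byte-identical across repeated runs", {
  set.seed(8)
  tree <- ape::root(ape::rtree(12), 1, resolve.root = TRUE)
  refs <- ref_df(sample(tree$tip.label, 4), "Glomus", "Glomus clarum")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_assignments(assign_taxonomy(tree, refs), f1)
  write_assignments(assign_taxonomy(tree, refs), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("species-level assignments always name a species housed with the query", {
  set.seed(13)
  for (rep in 1:20) {
    tree <- ape::root(ape::rtree(15), 1, resolve.root = TRUE)
    ref_ids <- sample(tree$tip.label, 5)
    refs <- rbind(ref_df(ref_ids[1:3], "Glomus", "Glomus clarum"),
                  ref_df(ref_ids[4:5], "Rhizophagus", "Rhizophagus irregularis"))
    a <- assign_taxonomy(tree, refs)
    sp_rows <- a[a$rank == "species", , drop = FALSE]
    for (i in seq_len(nrow(sp_rows)))
      expect_true(sp_rows$taxon[i] %in% refs$species)
  }
})

test_that("detect_novel_clades reports maximal query-only clades", {
  refs <- ref_df(c("r1", "r2"), "Glomus", "Glomus clarum")
  tr <- parse_newick(paste0("(((q1:1,q2:1):1,((q3:1,q4:1):1,(q5:1,q6:1):1):1):1,",
                            "(r1:1,r2:1):1);"))
  nc <- detect_novel_clades(tr, refs$seq_id)
  expect_equal(nrow(nc), 1)                       # nested clades collapse
  expect_setequal(nc$members[[1]], paste0("q", 1:6))
  # every query sister to a reference: nothing to report
  tr2 <- parse_newick("((q1:1,r1:1):1,(q2:1,r2:1):1);")
  expect_equal(nrow(detect_novel_clades(tr2, refs$seq_id)), 0)
  # oracle agreement on random instances
  set.seed(17)
  for (rep in 1:100) {
    tree <- ape::root(ape::rtree(sample(6:25, 1)), 1, resolve.root = TRUE)
    ref_ids <- sample(tree$tip.label, sample(2:4, 1))
    got <- detect_novel_clades(tree, ref_ids)$members
    want <- oracle_novel_clades(tree, ref_ids)
    expect_equal(length(got), length(want))
    for (s in want)
      expect_true(any(vapply(got, function(g) setequal(g, s), logical(1))))
  }
})

test_that("diagnostics attach long branches and private insertions", {
  # novel clade (q1..q3) carries a 12-column private insertion and a long stem
  refs <- ref_df(c("r1", "r2"), "Glomus", "Glomus clarum")
  tr <- parse_newick(paste0("(((q1:0.01,q2:0.01):0.005,q3:0.01):0.6,",
                            "(r1:0.01,(r2:0.01,q4:0.01):0.005):0.01);"))
  set.seed(4)
  core <- replicate(6, paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                             collapse = ""))
  ins <- c(rep("GGGGGGGGGGGG", 3), rep("------------", 3))
  rows <- stats::setNames(paste0(substr(core, 1, 20), ins, substr(core, 21, 40)),
                          c("q1", "q2", "q3", "r1", "r2", "q4"))
  a <- assign_taxonomy(tr, refs)
  a <- annotate_novel_clades(a, detect_novel_clades(tr, refs$seq_id))
  a <- annotate_diagnostics(a, tr, msa(rows), factor = 5)
  novel <- a[!is.na(a$novel_clade_id), ]
  expect_setequal(novel$asv_id, c("q1", "q2", "q3"))
  expect_true(all(novel$exclusive_insertion_cols == 12))
  expect_equal(a$exclusive_insertion_cols[a$asv_id == "q4"], 0L)
  expect_false(any(a$long_branch))   # the long branch is the clade stem, not a tip
  # no gaps, uniform branches: all diagnostics off
  tru <- parse_newick("((q1:1,r1:1):1,(q2:1,r2:1):1);")
  rows2 <- stats::setNames(rep(substr(core[1], 1, 30), 4), c("q1", "r1", "q2", "r2"))
  a2 <- assign_taxonomy(tru, refs)
  a2 <- annotate_diagnostics(a2, tru, msa(rows2))
  expect_false(any(a2$long_branch))
  expect_true(all(a2$exclusive_insertion_cols == 0))
  # tree/alignment tip mismatch errors with the symmetric difference
  expect_error(annotate_diagnostics(a2, tru, msa(rows)), "differ")
})

test_that("off-target queries on the outgroup side or root edge are removed", {
  refs <- rbind(ref_df("r1", "Glomus", "Glomus clarum"),
                ref_df("P1", "Paraglomus", "Paraglomus brasilianum",
                       family = "Paraglomeraceae", order = "Paraglomerales"),
                ref_df("P2", "Paraglomus", "Paraglomus occultum",
                       family = "Paraglomeraceae", order = "Paraglomerales"))
  tr <- parse_newick(paste0("(((P1:1,P2:1):1,bad1:1):1,",
                            "((q1:1,r1:1):1,q2:1):1);"))
  a <- assign_taxonomy(tr, refs)
  res <- filter_off_target(a, tr, c("P1", "P2"))
  expect_setequal(res$removed$asv_id, "bad1")
  expect_setequal(res$kept$asv_id, c("q1", "q2"))
  # a query attached to the root edge itself is removed
  tr2 <- parse_newick("(stray:1,((P1:1,P2:1):1,(q1:1,r1:1):1):1);")
  a2 <- assign_taxonomy(tr2, refs)
  res2 <- filter_off_target(a2, tr2, c("P1", "P2"))
  expect_true("stray" %in% res2$removed$asv_id)
  expect_true("q1" %in% res2$kept$asv_id)
})
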