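# Tree I/O and algorithms: newick round trips, JC distances, NJ recovery,
# outgroup rooting, monophyly, long-branch flagging.

test_that("parse_newick reads supports and round-trips structure", {
  tr <- parse_newick("((A:1,B:1)90:0.5,C:2);")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(node_support(tr)[2], 90)
  set.seed(5)
  big <- ape::rtree(50)
  big$node.label <- as.character(sample(50:100, big$Nnode, replace = TRUE))
  rt <- parse_newick(write_newick(big))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rt), ape::unroot(big))), 0)
  expect_equal(sort(rt$edge.length), sort(big$edge.length), tolerance = 1e-9)
  expect_equal(rt$node.label, big$node.label)
  expect_error(parse_newick("(A,B"), "parse error")
  expect_error(parse_newick("((A:1,B:1),A:2);"), "duplicate")
  expect_warning(parse_newick("((A:1,B:1)0.97:0.5,C:2);"), "rescaling")
})

test_that("jc_distance matches the closed form and handles saturation", {
  m <- msa(c(a = strrep("A", 20), b = strrep("A", 20)))
  expect_equal(jc_distance(m)["a", "b"], 0)
  # p = 0.1 over 100 sites
  s <- paste(rep("ACGTT", 20), collapse = "")
  s2 <- paste0(strrep("G", 10), substr(s, 11, 100))
  s1 <- paste0(strrep("C", 10), substr(s, 11, 100))
  d <- jc_distance(msa(c(a = s1, b = s2)))["a", "b"]
  expect_equal(d, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  # overlap restricted to both-residue columns
  g <- msa(c(a = "AC-T", b = "A-GT"))
  expect_equal(jc_distance(g)["a", "b"], 0)   # only columns 1 and 4 overlap
  expect_error(jc_distance(msa(c(a = "AC--", b = "--GT"))), "no overlapping")
  sat <- msa(c(a = strrep("ACGTA", 4), b = strrep("CGTAC", 4)))  # p = 1
  expect_warning(ds <- jc_distance(sat), "saturated")
  expect_equal(ds["a", "b"], 5)
})

test_that("jc_distance agrees with ape's JC69 on gapless alignments", {
  set.seed(21)
  # related sequences (iid rows would sit at saturation): mutate copies of
  # one ancestor at ~5% per site
  anc <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  mat <- t(vapply(1:6, function(i) {
    s <- anc
    hit <- runif(200) < 0.05
    s[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    s
  }, character(200)))
  rownames(mat) <- paste0("s", 1:6)
  m <- msa(mat)
  ours <- jc_distance(m)
  bin <- ape::as.DNAbin(unclass(m))
  theirs <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)], tolerance = 1e-9)
})

test_that("nj_tree recovers additive topologies and the 3-taxon formulas", {
  true <- parse_newick("((A:1,B:2):1,(C:3,D:1):1);")
  dm <- ape::cophenetic.phylo(true)
  nj <- nj_tree(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), nj)), 0)
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  t3 <- nj_tree(d3)
  # 3-point formulas: a = (dAB + dAC - dBC)/2 etc.
  bl <- stats::setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))
  tie <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4])); diag(tie) <- 0
  expect_s3_class(nj_tree(tie), "phylo")
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("NJ on JC distances recovers the generating topology at low divergence", {
  set.seed(42)
  true <- ape::rtree(8)
  true$edge.length <- stats::runif(nrow(true$edge), 0.02, 0.06)
  hits <- 0
  for (rep in 1:100) {
    sim <- phangorn::simSeq(true, l = 800, type = "DNA")
    mat <- toupper(as.character(sim))
    m <- msa(mat)
    nj <- nj_tree(jc_distance(m))
    if (ape::dist.topo(ape::unroot(true), nj) == 0) hits <- hits + 1
  }
  expect_gte(hits / 100, 0.95)
})

test_that("root_on_outgroup places the root and preserves bipartitions", {
  tr <- parse_newick("(((A:1,B:1):1,C:1):1,(P1:1,P2:1):1,D:3);")
  r1 <- root_on_outgroup(tr, "D")
  expect_true(ape::is.rooted(r1))
  expect_true(is_monophyletic(r1, setdiff(tr$tip.label, "D")))
  # cherry outgroup: root on the edge above the cherry
  r2 <- root_on_outgroup(tr, c("P1", "P2"))
  kids <- r2$edge[r2$edge[, 1] == ape::Ntip(r2) + 1, 2]
  sides <- lapply(kids, function(k)
    r2$tip.label[phangorn::Descendants(r2, k, "tips")[[1]]])
  expect_true(any(vapply(sides, function(s) setequal(s, c("P1", "P2")), logical(1))))
  # unrooted split set is preserved by rooting
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(r2), ape::unroot(tr))), 0)
  # non-monophyletic outgroup falls back with a warning
  tr2 <- parse_newick("((P1:1,C:1):1,(P2:1,D:1):1,E:1);")
  expect_warning(r3 <- root_on_outgroup(tr2, c("P1", "P2")), "not monophyletic")
  expect_true(ape::is.rooted(r3))
  expect_error(root_on_outgroup(tr, tr$tip.label), "proper subset")
  expect_error(root_on_outgroup(tr, "nope"), "not in tree")
})

test_that("is_monophyletic matches brute-force clade enumeration", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, "C"))
  expect_error(is_monophyletic(tr, "Z"), "unknown tip")
  set.seed(7)
  for (rep in 1:40) {
    tree <- ape::root(ape::rtree(sample(5:20, 1)), 1, resolve.root = TRUE)
    for (k in 1:25) {
      tips <- sample(tree$tip.label, sample(2:ape::Ntip(tree), 1))
      expect_identical(is_monophyletic(tree, tips),
                       oracle_is_monophyletic(tree, tips))
    }
  }
})

test_that("long_branch_tips flags against the median tip branch", {
  star <- ape::stree(6, type = "star")
  star$edge.length <- c(1, 1, 1, 1, 1, 10)
  expect_equal(long_branch_tips(star, factor = 5), star$tip.label[6])
  uni <- star; uni$edge.length <- rep(1, 6)
  expect_length(long_branch_tips(uni, factor = 5), 0)
  expect_length(long_branch_tips(star, factor = Inf), 0)
  zero <- star; zero$edge.length <- rep(0, 6)
  expect_warning(res <- long_branch_tips(zero), "zero")
  expect_length(res, 0)
  # clade scope returns all tips under a flagged internal edge
  tr <- parse_newick("((A:1,B:1):20,(C:1,D:1):1);")
  expect_equal(long_branch_tips(tr, factor = 5, scope = "clades"), c("A", "B"))
})
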