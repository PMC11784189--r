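# Alignment operations: gap fractions, primer-window location, window and
# gap-stringency trimming, clade-exclusive insertion columns.

AML1_SEQ <- "ATCAACTTTCGATGGTAGGATAGA"
AML2_SEQ <- "GAACCCAAACACTTTGGTTTCC"

# gapless amplicon with the forward primer at 1-based offset `at` and the
# reverse-complemented reverse primer ending at position `len`
amplicon_row <- function(len = 300, at = 11) {
  set.seed(99)
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  f <- strsplit(AML1_SEQ, "")[[1]]
  r <- strsplit(amfphylo:::revcomp(AML2_SEQ), "")[[1]]
  s[at:(at + length(f) - 1)] <- f
  s[(len - length(r) + 1):len] <- r
  paste(s, collapse = "")
}

test_that("column_gap_fraction counts gaps per column", {
  m <- msa(c(a = "A-", b = "AA"))
  expect_equal(column_gap_fraction(m), c(0, 0.5))
  g <- msa(c(a = "ACGT", b = "ACGT"))
  expect_equal(column_gap_fraction(g), rep(0, 4))
  m2 <- msa(c(a = "A-", b = "A-"))
  expect_equal(column_gap_fraction(m2)[2], 1)
})

test_that("locate_primer_window finds the amplicon span", {
  len <- 300
  rows <- stats::setNames(rep(amplicon_row(len), 4), paste0("s", 1:4))
  m <- msa(rows)
  w <- locate_primer_window(m, primer_pair())
  expect_equal(unname(w), c(11, len))          # both primer sites included
  expect_identical(msa_strings(trim_to_window(m, w))[[1]],
                   substr(rows[[1]], 11, len))
  # one mismatch in the forward site, max_mismatches = 2: same window
  s2 <- rows
  substr(s2[2], 13, 13) <- "T"                 # mutate inside AML1 site
  w2 <- locate_primer_window(msa(s2), primer_pair(max_mismatches = 2))
  expect_equal(w2, w)
  # primers absent everywhere -> error
  noprim <- msa(c(a = strrep("AC", 150), b = strrep("AC", 150)))
  expect_error(locate_primer_window(noprim), "not localizable")
})

test_that("primer offsets are mapped through each row's gap pattern", {
  base <- amplicon_row(200)
  gapped <- paste0(substr(base, 1, 5), "-----", substr(base, 6, 200))
  m <- msa(c(a = gapped, b = paste0(substr(base, 1, 5), "AAAAA",
                                    substr(base, 6, 200))))
  w <- locate_primer_window(m, primer_pair(), min_fraction = 0.5)
  # forward primer at ungapped offset 11 in row a maps past its 5-column
  # gap block to column 16; both rows end their amplicon at column 205
  expect_equal(unname(w), c(16, 205))
})

test_that("trim_to_window slices columns and drops rows made all-gap", {
  m <- msa(c(a = "ACGT", b = "AC-T", c = "AGGT"))
  expect_equal(unclass(trim_to_window(m, c(1, 4))), unclass(m))   # identity
  t13 <- trim_to_window(m, c(2, 3))
  expect_equal(ncol(t13), 2)
  expect_equal(msa_strings(t13)[["a"]], "CG")
  expect_warning(dropped <- trim_to_window(msa(c(a = "A--T", b = "ACGT")), c(2, 3)),
                 "all-gap")
  expect_equal(rownames(dropped), "b")
  expect_error(trim_to_window(m, c(3, 2)), "invalid window")
})

test_that("nested window trims compose to the inner window", {
  m <- random_alignment(6, 40, gap_prob = 0.1)
  ab <- trim_to_window(trim_to_window(m, c(5, 35)), c(3, 20))
  direct <- trim_to_window(m, c(7, 24))
  expect_equal(unclass(ab), unclass(direct))
})

test_that("gap_trim matches the per-column oracle and threshold semantics", {
  m <- msa(c(a = "A-", b = "AA"))
  expect_equal(ncol(gap_trim(m, 0)$msa), 1)        # any gap removed at 0
  expect_equal(ncol(gap_trim(m, 0.6)$msa), 2)      # 0.5 < 0.6 kept
  expect_equal(ncol(gap_trim(m, 0.5)$msa), 1)      # 0.5 >= 0.5 removed
  gapless <- msa(c(a = "ACGT", b = "ACGT"))
  for (t in c(0.9, 0.5, 0.1, 0))
    expect_equal(unclass(gap_trim(gapless, t)$msa), unclass(gapless))
  set.seed(11)
  for (rep in 1:20) {
    m <- random_alignment(sample(3:20, 1), sample(5:50, 1), gap_prob = 0.3)
    t <- sample(c(0, 0.1, 0.25, 0.5, 0.9, 1), 1)
    kept_oracle <- oracle_gap_trim_kept(unclass(m), t)
    if (!any(kept_oracle)) {
      expect_error(gap_trim(m, t), "fully trimmed")
    } else {
      gt <- suppressWarnings(gap_trim(m, t))
      expect_equal(gt$col_map$kept, kept_oracle)
      expect_equal(unclass(gt$msa), unclass(m)[, kept_oracle, drop = FALSE])
      expect_equal(gt$col_map$new[kept_oracle], seq_len(sum(kept_oracle)))
    }
  }
})

test_that("removed-column sets are nested across decreasing stringency thresholds", {
  set.seed(12)
  for (rep in 1:10) {
    m <- random_alignment(8, 60, gap_prob = 0.25)
    removed <- lapply(c(0.9, 0.5, 0.1, 0), function(t) {
      res <- tryCatch(suppressWarnings(gap_trim(m, t)), error = function(e) NULL)
      if (is.null(res)) seq_len(ncol(m)) else which(!res$col_map$kept)
    })
    for (k in 1:3)
      expect_true(all(removed[[k]] %in% removed[[k + 1]]))
  }
})

test_that("clade_exclusive_columns finds private insertion blocks", {
  # 12-column insertion private to 3 of 10 rows
  set.seed(3)
  core <- replicate(10, paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                              collapse = ""))
  ins <- vapply(1:10, function(i)
    if (i <= 3) paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
    else strrep("-", 12), character(1))
  rows <- stats::setNames(paste0(substr(core, 1, 15), ins, substr(core, 16, 30)),
                          paste0("r", 1:10))
  m <- msa(rows)
  expect_equal(clade_exclusive_columns(m, c("r1", "r2", "r3")), 16:27)
  # the complementary clade shares no exclusive column with the clade
  comp <- clade_exclusive_columns(m, paste0("r", 4:10))
  expect_length(intersect(comp, 16:27), 0)
  gapless <- msa(c(a = "ACGT", b = "AGGT", c = "ACGA"))
  expect_length(clade_exclusive_columns(gapless, c("a", "b")), 0)
  expect_error(clade_exclusive_columns(m, paste0("r", 1:10)), "proper subset")
  # definitional: a column with residues only in the clade is reported
  # even when only half of the clade rows carry it (f_in = 0.5)
  half <- rows
  substr(half["r1"], 16, 16) <- "-"
  expect_true(16 %in% clade_exclusive_columns(msa(half), c("r1", "r2", "r3")))
})

test_that("alignment I/O round-trips through gapped FASTA", {
  m <- random_alignment(5, 25, gap_prob = 0.2)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_msa(m, f)
  expect_equal(unclass(read_msa(f)), unclass(m))
})
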