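test_that("self-alignment is the identity with score match * length", {
  for (x in c("ACDEF", "MRHNY", "W")) {
    aln <- globalAlign(x, x)
    expect_identical(aln$a, x)
    expect_identical(aln$b, x)
    expect_equal(aln$score, nchar(x))
  }
})

test_that("a single internal deletion opens one gap", {
  aln <- globalAlign("ACDEF", "ACEF")
  expect_equal(aln$score, 4 * 1 - 5)  # 4 matches + one length-1 gap
  expect_identical(aln$a, "ACDEF")
  expect_equal(nchar(aln$b), 5L)
  expect_equal(lengths(regmatches(aln$b, gregexpr("-", aln$b))), 1L)
})

test_that("alignment scores are symmetric and match exhaustive search", {
  set.seed(41)
  aas <- c("A", "C", "D", "R", "S", "*")
  for (rep in 1:10) {
    a <- paste(sample(aas, sample(2:7, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:7, 1), replace = TRUE), collapse = "")
    got <- globalAlign(a, b)$score
    expect_equal(got, globalAlign(b, a)$score)
    expect_equal(got, oracleAlignScore(a, b))
  }
  expect_error(globalAlign("AC?", "AC"), "invalid residue")
})

test_that("stop symbols never match, even against themselves", {
  expect_equal(globalAlign("A*A", "A*A")$score, 2 * 1 - 1)
})

test_that("identical sequences align gap-free in the progressive MSA", {
  msa <- progressiveMsa(c(a = "MRHNYNK", b = "MRHNYNK", c = "MRHNYNK"))
  expect_true(all(!grepl("-", msa)))
  tiers <- conservationTiers(msa)
  expect_equal(tiers$pct_all_conserved, 100)
})

test_that("one deleted residue in one row yields exactly one gap column", {
  msa <- progressiveMsa(c(s1 = "MRHNYNKLHL", s2 = "MRHNNKLHL",
                          s3 = "MRHNYNKLHL"))
  expect_equal(unique(nchar(msa)), 10L)
  gapCols <- which(strsplit(msa[["s2"]], "")[[1]] == "-")
  expect_length(gapCols, 1L)
  expect_false(any(grepl("-", msa[c("s1", "s3")])))
})

test_that("column tiers implement the all/n-1 shading rule", {
  msa <- c(a = "MRHNY", b = "MRHNY", c = "MRHNY", d = "MRHNY", e = "MRHQY")
  tiers <- conservationTiers(msa)
  expect_identical(tiers$columns$tier,
                   c("all_conserved", "all_conserved", "all_conserved",
                     "near_conserved", "all_conserved"))
  expect_equal(tiers$pct_all_conserved, 80)
  # row order never matters
  tiers2 <- conservationTiers(msa[c(3, 5, 1, 2, 4)])
  expect_identical(sort(tiers2$columns$tier), sort(tiers$columns$tier))
  # a gap blocks full conservation
  tiers3 <- conservationTiers(c(a = "M-R", b = "MAR", c = "MAR"))
  expect_identical(tiers3$columns$tier,
                   c("all_conserved", "near_conserved", "all_conserved"))
  expect_error(conservationTiers(c("AB", "ABC")), "ragged")
})

test_that("removing a duplicated row cannot reduce full conservation", {
  set.seed(53)
  aas <- c("A", "C", "D", "R", "S")
  for (rep in 1:6) {
    base <- vapply(1:3, function(i)
      paste(sample(aas, 12, replace = TRUE), collapse = ""), character(1))
    names(base) <- paste0("s", 1:3)
    withDup <- c(base, s4 = unname(base[1]))
    pctDup <- conservationTiers(progressiveMsa(withDup))$pct_all_conserved
    pct <- conservationTiers(progressiveMsa(base))$pct_all_conserved
    expect_gte(pct, pctDup)
  }
})

test_that("ortholog-style divergence shades like the published figure", {
  # five primate-like variants of one peptide: most columns black, a few
  # single-species substitutions gray
  seqs <- c(hsap = "MRHNYNKLHLPTTNRPKIAH",
            ptro = "MRHNYNKLHLPTTNRPKIAH",
            ggor = "MRHNYNKLHLPTANRPKIAH",
            ppyg = "MRHNYNKLHLPTTNRPKIAH",
            mmul = "MRHNYSKLHLPTTNRPKIAH")
  msa <- progressiveMsa(seqs)
  tiers <- conservationTiers(msa)
  expect_equal(sum(tiers$columns$tier == "near_conserved"), 2L)
  expect_equal(sum(tiers$columns$tier == "all_conserved"), 18L)
  out <- withr::local_tempfile(fileext = ".txt")
  writeShadedAlignment(msa, tiers, out)
  txt <- readLines(out)
  expect_true(any(grepl("#", txt, fixed = TRUE)))
  faOut <- withr::local_tempfile(fileext = ".fasta")
  writeMsaFasta(msa, faOut)
  expect_equal(length(Biostrings::readBStringSet(faOut)), 5L)
})
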