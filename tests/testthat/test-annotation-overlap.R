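mod <- loadGeneticCode("vertebrate_mito_modified")

# small fixture: one plus gene, one minus gene, one rRNA on a 900-nt circle
fixAnn <- geneAnnotations(
  name = c("geneA", "geneB", "rrn1"),
  feature_type = c("protein_coding", "protein_coding", "rRNA"),
  start = c(101, 401, 701), end = c(250, 520, 800),
  strand = c("+", "-", "+"))

mkOrf <- function(start, end, strand, aaLen, aa = strrep("K", aaLen)) {
  data.frame(orf_id = "o1", genome_id = "g", strand = strand,
             frame = frameOf(start, strand, 900), start = start,
             end_no_stop = end, has_stop = TRUE, wraps_origin = FALSE,
             mode = "stop_to_stop", aa_sequence = aa, aa_length = aaLen,
             nt_length_with_stop = 3 * aaLen + 3, stringsAsFactors = FALSE)
}

test_that("an ORF identical to a reference gene matches it in frame 0", {
  # geneA is 150 nt: 49 codons + stop
  o <- mkOrf(101, 247, "+", 49)
  cl <- classifyOrfs(o, fixAnn, 900)
  expect_identical(cl$category, "matches_reference")
  expect_identical(cl$host_feature, "geneA")
  expect_equal(cl$frame_offset, 0L)
  # minus-strand reference: geneB spans 401..520, 5' end at 520
  o2 <- mkOrf(520, 404, "-", 39)
  cl2 <- classifyOrfs(o2, fixAnn, 900)
  expect_identical(cl2$category, "matches_reference")
  expect_identical(cl2$host_feature, "geneB")
})

test_that("sense frameshifts, antisense and RNA residents are recognised", {
  fs <- mkOrf(101 + 7, 101 + 7 + 29, "+", 10)
  clFs <- classifyOrfs(fs, fixAnn, 900)
  expect_identical(clFs$category, "sense_frameshift")
  expect_equal(clFs$frame_offset, 7 %% 3)
  as <- mkOrf(220, 191, "-", 10)  # minus ORF inside plus geneA
  clAs <- classifyOrfs(as, fixAnn, 900)
  expect_identical(clAs$category, "antisense")
  expect_true(is.na(clAs$frame_offset))
  rr <- mkOrf(710, 739, "+", 10)
  expect_identical(classifyOrfs(rr, fixAnn, 900)$category, "within_rRNA")
  ig <- mkOrf(850, 879, "+", 10)
  clIg <- classifyOrfs(ig, fixAnn, 900)
  expect_identical(clIg$category, "intergenic")
  expect_equal(clIg$overlap_nt, 0L)
})

test_that("frame offsets are additive mod 3 and reject cross-strand calls", {
  expect_equal(frameOffset(100, 100), 0L)
  expect_equal(frameOffset(100 + 797, 100), 797 %% 3)
  expect_equal(frameOffset(104, 100), 1L)
  expect_error(frameOffset(1, 2, sameStrand = FALSE), "antisense")
  set.seed(13)
  for (rep in 1:20) {
    abc <- sample(1:1000, 3)
    expect_equal((frameOffset(abc[1], abc[2]) +
                    frameOffset(abc[2], abc[3])) %% 3,
                 frameOffset(abc[1], abc[3]))
    expect_equal(frameOffset(abc[1], abc[2], strand = "-"),
                 frameOffset(abc[2], abc[1]))
  }
})

test_that("overlap ties produce multi_feature with all hosts listed", {
  ann <- geneAnnotations(name = c("g1", "g2"),
                         feature_type = c("protein_coding", "protein_coding"),
                         start = c(1, 151), end = c(150, 300), strand = "+")
  # 60-nt ORF straddling the boundary evenly: 30 nt in each gene
  o <- mkOrf(121, 180, "+", 20)
  cl <- classifyOrfs(o, ann, 400)
  expect_identical(cl$category, "multi_feature")
  expect_identical(cl$host_feature, "g1,g2")
})

test_that("filtering removes reference and known ORFs and nothing else", {
  orfs <- rbind(mkOrf(101, 247, "+", 49),
                mkOrf(108, 137, "+", 10, aa = "KNOWNPEPT1"),
                mkOrf(710, 739, "+", 10, aa = "RNARESIDENT"),
                mkOrf(850, 879, "+", 10, aa = "NEWCANDIDATE"))
  known <- data.frame(name = "kp1", aa_sequence = "KNOWNPEPT1",
                      start = NA, end = NA, strand = NA,
                      stringsAsFactors = FALSE)
  kept <- filterUnannotated(orfs, fixAnn, 900, knownOrfs = known)
  expect_setequal(kept$aa_sequence, c("RNARESIDENT", "NEWCANDIDATE"))
  expect_equal(nrow(kept) + 2L, nrow(orfs))  # partition, no loss
  # coordinate-based known matching
  known2 <- data.frame(name = "kp2", aa_sequence = NA,
                       start = 850, end = 879, strand = "+",
                       stringsAsFactors = FALSE)
  kept2 <- filterUnannotated(orfs, fixAnn, 900, knownOrfs = known2)
  expect_false("NEWCANDIDATE" %in% kept2$aa_sequence)
  # reference genes alone vanish entirely
  refOnly <- filterUnannotated(mkOrf(101, 247, "+", 49), fixAnn, 900)
  expect_equal(nrow(refOnly), 0L)
})

test_that("classification is invariant under joint genome rotation", {
  set.seed(44)
  sim <- generateGenome(600, mod,
    plants = list(plantSpec("reference_gene", 60, name = "gA"),
                  plantSpec("sense_frameshift", 22, name = "a1",
                            host = "gA", frameOffset = 1)),
    seed = 99)
  L <- length(sim$genome)
  orfs <- scanOrfs(sim$genome, mod, minAa = 20)
  cl <- classifyOrfs(orfs, sim$annotations, L)
  k <- 121
  rot <- function(p) ((p - k - 1) %% L) + 1
  s <- genomeSequence(sim$genome)
  g2 <- circularGenome(paste0(substring(s, k + 1, L), substring(s, 1, k)))
  ann2 <- sim$annotations
  ann2$start <- rot(ann2$start); ann2$end <- rot(ann2$end)
  ann2$wraps <- ann2$start > ann2$end
  orfs2 <- scanOrfs(g2, mod, minAa = 20)
  cl2 <- classifyOrfs(orfs2, ann2, L)
  key <- function(d, pos) sprintf("%s|%s|%s", d$category, d$host_feature,
                                  d$frame_offset)
  expect_setequal(sprintf("%s|%s", key(cl), cl$aa_sequence),
                  sprintf("%s|%s", key(cl2), cl2$aa_sequence))
})

test_that("GFF3 annotations read back with mapped feature types", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrM\ttest\tgene\t101\t250\t.\t+\t.\tID=gene1;Name=geneA",
    "chrM\ttest\trRNA\t701\t800\t.\t+\t.\tID=r1;Name=rrn1",
    "chrM\ttest\ttRNA\t300\t370\t.\t-\t.\tID=t1;Name=trnX",
    "chrM\ttest\tD_loop\t1\t100\t.\t+\t.\tID=d1;Name=dloop",
    "chrM\ttest\tregion\t1\t900\t.\t+\t.\tID=whole"), path)
  ann <- readAnnotationsGff3(path)
  expect_equal(nrow(ann), 4L)  # 'region' dropped
  expect_setequal(ann$feature_type,
                  c("protein_coding", "rRNA", "tRNA", "D_loop"))
  expect_equal(ann$start[ann$name == "geneA"], 101L)
  expect_identical(ann$strand[ann$name == "trnX"], "-")
})
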