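mod <- loadGeneticCode("vertebrate_mito_modified")

test_that("generation is deterministic under a seed and varies across seeds", {
  plants <- list(plantSpec("reference_gene", 40, name = "g1"),
                 plantSpec("antisense", 21, name = "a1", host = "g1"))
  s1 <- generateGenome(450, mod, plants, seed = 42)
  s2 <- generateGenome(450, mod, plants, seed = 42)
  expect_identical(genomeSequence(s1$genome), genomeSequence(s2$genome))
  expect_identical(s1$truth, s2$truth)
  s3 <- generateGenome(450, mod, plants, seed = 43)
  expect_false(identical(genomeSequence(s1$genome),
                         genomeSequence(s3$genome)))
})

test_that("zero stop density and no plants leave frame 1 as one circular ORF", {
  sim <- generateGenome(300, mod, backgroundStopDensity = 0, seed = 5)
  o <- scanOrfs(sim$genome, mod, minAa = 1)
  f1 <- o[o$strand == "+" & o$frame == 1, ]
  expect_equal(nrow(f1), 1L)
  expect_true(f1$wraps_origin)
  expect_false(f1$has_stop)
  expect_equal(f1$aa_length, 100L)
})

test_that("planted ORFs are recovered at their exact coordinates", {
  plants <- list(plantSpec("reference_gene", 100, name = "geneA"),
                 plantSpec("sense_frameshift", 30, name = "alt2",
                           host = "geneA", frameOffset = 2))
  sim <- generateGenome(900, mod, plants, seed = 7)
  L <- length(sim$genome)
  orfs <- scanOrfs(sim$genome, mod, minAa = 20)
  cl <- classifyOrfs(orfs, sim$annotations, L)
  fs <- cl[cl$category == "sense_frameshift", ]
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$frame_offset, 2L)
  truthFs <- sim$truth[sim$truth$name == "alt2", ]
  expect_equal(fs$start, truthFs$start)
  expect_equal(fs$end_no_stop, truthFs$end_no_stop)
  expect_identical(fs$aa_sequence, truthFs$aa_sequence)
  # ATG-initiated scanning finds the same planted record
  atg <- scanOrfs(sim$genome, mod, minAa = 20, mode = "atg_initiated")
  expect_true(any(atg$start == truthFs$start &
                    atg$end_no_stop == truthFs$end_no_stop))
})

test_that("infeasible plants fail with an informative error", {
  expect_error(generateGenome(300, mod,
    plants = list(plantSpec("reference_gene", 20, name = "tiny"),
                  plantSpec("sense_frameshift", 30, name = "big",
                            host = "tiny", frameOffset = 1)),
    seed = 1), "big")
  expect_error(generateGenome(90, mod,
    plants = list(plantSpec("reference_gene", 100, name = "huge")),
    seed = 1), "footprint")
  expect_error(generateGenome(100, mod, seed = 1), "multiple of 3")
  expect_error(generateGenome(300, mod), "seed")
  expect_error(plantSpec("sense_frameshift", 10), "host")
})

test_that("the mitochondria-like layout has the full annotation complement", {
  sim <- emulateMitoLayout(seed = 11)
  ann <- sim$annotations
  expect_equal(nrow(ann), 38L)
  expect_equal(sum(ann$feature_type == "protein_coding"), 13L)
  expect_equal(sum(ann$feature_type == "rRNA"), 2L)
  expect_equal(sum(ann$feature_type == "tRNA"), 22L)
  expect_equal(sum(ann$feature_type == "D_loop"), 1L)
  expect_setequal(unique(ann$strand), c("+", "-"))
  expect_gt(length(sim$genome), 16000L)
  expect_equal(length(sim$genome) %% 3L, 0L)
  kinds <- sim$truth$kind
  expect_setequal(unique(kinds),
                  c("reference_gene", "sense_frameshift", "antisense",
                    "rna_resident", "intergenic"))
})

test_that("the layout's truth table is the complete >=20-aa ORF catalogue", {
  sim <- emulateMitoLayout(seed = 23)
  L <- length(sim$genome)
  orfs <- scanOrfs(sim$genome, mod, minAa = 20)
  # every scanned record is genuinely stop-free at its coordinates
  SS <- paste0(genomeSequence(sim$genome), genomeSequence(sim$genome))
  for (i in seq_len(nrow(orfs))) {
    rec <- orfs[i, ]
    lo <- min(rec$start, rec$end_no_stop)
    ntStr <- substring(SS, lo, lo + 3 * rec$aa_length - 1)
    if (rec$strand == "-") ntStr <- revComp(ntStr)
    expect_identical(translateCds(ntStr, mod)$aa, rec$aa_sequence)
  }
  # scan finds exactly the planted records (13 genes + altORFs)
  expect_equal(nrow(orfs), nrow(sim$truth))
  kept <- filterUnannotated(orfs, sim$annotations, L)
  alt <- sim$truth[sim$truth$kind != "reference_gene", ]
  expect_equal(nrow(kept), nrow(alt))
  key <- function(d) sprintf("%s|%d|%d", d$strand, d$start, d$end_no_stop)
  expect_setequal(key(kept), key(alt))
  # categories and frame offsets match the truth table
  m <- match(key(alt), key(kept))
  expect_identical(kept$category[m], alt$category)
  expect_identical(kept$host_feature[m], alt$host)
  expect_equal(kept$frame_offset[m], alt$frame_offset)
})

test_that("recovery holds across seeds (round-trip property)", {
  for (seed in c(101, 202, 303)) {
    sim <- emulateMitoLayout(seed = seed)
    L <- length(sim$genome)
    orfs <- scanOrfs(sim$genome, mod, minAa = 20)
    cl <- classifyOrfs(orfs, sim$annotations, L)
    key <- function(d) sprintf("%s|%d|%d", d$strand, d$start, d$end_no_stop)
    m <- match(key(sim$truth), key(cl))
    expect_false(anyNA(m))
    expect_identical(cl$category[m], sim$truth$category)
  }
})
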