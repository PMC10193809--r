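std <- loadGeneticCode("standard")
mod <- loadGeneticCode("vertebrate_mito_modified")

test_that("a hand-checkable linear genome yields the expected frame-1 ORF", {
  g <- circularGenome("TAAATGGCATAG", topology = "linear")
  o <- scanOrfs(g, std, minAa = 1)
  f1 <- o[o$strand == "+" & o$frame == 1, ]
  expect_equal(nrow(f1), 1L)
  expect_equal(f1$start, 4L)
  expect_equal(f1$end_no_stop, 9L)
  expect_identical(f1$aa_sequence, "MA")
  expect_true(f1$has_stop)
  expect_equal(f1$nt_length_with_stop, 9L)
  expect_error(scanOrfs(circularGenome("AT"), std), "shorter than 3")
  expect_error(scanOrfs(g, std, minAa = 0), "minAa")
})

test_that("scan output matches the brute-force oracle on random genomes", {
  set.seed(101)
  for (rep in 1:15) {
    g <- randomGenome(sample(60:300, 1))
    minAa <- sample(1:5, 1)
    expect_scan_matches_oracle(g, mod, minAa, "stop_to_stop")
    expect_scan_matches_oracle(g, mod, minAa, "atg_initiated")
    expect_scan_matches_oracle(g, mod, minAa, "atg_initiated",
                               allDown = TRUE)
  }
  # linear topology too
  for (rep in 1:5) {
    g <- randomGenome(sample(60:200, 1), topology = "linear")
    expect_scan_matches_oracle(g, std, 2, "stop_to_stop")
    expect_scan_matches_oracle(g, std, 2, "atg_initiated")
  }
})

test_that("rotating a circular genome rotates coordinates and nothing else", {
  set.seed(7)
  for (rep in 1:8) {
    L <- sample(seq(90, 240, by = 3), 1)
    g <- randomGenome(L)
    k <- sample(seq_len(L - 1), 1)
    s <- genomeSequence(g)
    g2 <- circularGenome(paste0(substring(s, k + 1, L),
                                substring(s, 1, k)), id = "rot")
    o1 <- scanOrfs(g, mod, minAa = 3)
    o2 <- scanOrfs(g2, mod, minAa = 3)
    # phase of a wholly stop-free frame cycle is coordinate-dependent, so
    # compare those by count only and everything else exactly
    expect_equal(sum(!o1$has_stop), sum(!o2$has_stop))
    o1 <- o1[o1$has_stop, ]; o2 <- o2[o2$has_stop, ]
    expect_setequal(sort(o1$aa_sequence), sort(o2$aa_sequence))
    mapPos <- function(p) ((p - k - 1) %% L) + 1
    expect_setequal(
      sprintf("%s|%d|%d|%s", o1$strand, mapPos(o1$start),
              mapPos(o1$end_no_stop), o1$aa_sequence),
      sprintf("%s|%d|%d|%s", o2$strand, o2$start, o2$end_no_stop,
              o2$aa_sequence))
  }
})

test_that("scanning the reverse complement mirrors strands and coordinates", {
  set.seed(21)
  for (rep in 1:8) {
    g <- randomGenome(sample(60:240, 1))
    L <- length(g)
    g2 <- circularGenome(revComp(genomeSequence(g)), id = "rc")
    o1 <- scanOrfs(g, mod, minAa = 3)
    o2 <- scanOrfs(g2, mod, minAa = 3)
    mirror <- function(d) sprintf("%s|%d|%d|%s",
                                  ifelse(d$strand == "+", "-", "+"),
                                  L - d$start + 1, L - d$end_no_stop + 1,
                                  d$aa_sequence)
    expect_setequal(mirror(o1),
                    sprintf("%s|%d|%d|%s", o2$strand, o2$start,
                            o2$end_no_stop, o2$aa_sequence))
  }
})

test_that("stop-to-stop records never overlap within a frame and round-trip", {
  set.seed(33)
  for (rep in 1:6) {
    g <- randomGenome(sample(seq(90, 300, by = 3), 1))
    L <- length(g)
    o <- scanOrfs(g, mod, minAa = 2)
    SS <- paste0(genomeSequence(g), genomeSequence(g))
    # ascending-coordinate first base of the coding arc
    beg <- ifelse(o$strand == "+", o$start, o$end_no_stop)
    for (i in seq_len(nrow(o))) {
      rec <- o[i, ]
      ntStr <- substring(SS, beg[i], beg[i] + 3 * rec$aa_length - 1)
      if (rec$strand == "-") ntStr <- revComp(ntStr)
      expect_identical(translateCds(ntStr, mod)$aa, rec$aa_sequence)
    }
    for (fr in unique(o$frame)) {
      sel <- o$frame == fr
      covered <- unlist(lapply(which(sel), function(i) {
        (beg[i] - 1 + seq_len(3 * o$aa_length[i]) - 1) %% L
      }))
      expect_false(any(duplicated(covered)))
    }
  }
})

test_that("downstream start codons surface one record per in-frame ATG", {
  # run: ATG GCA ATG TAC TAA inside stop-flanked frame 1
  g <- circularGenome(paste0("TAA", "ATGGCAATGTAC", "TAA", "GGG"),
                      topology = "linear")
  all <- scanOrfs(g, std, minAa = 1, mode = "atg_initiated",
                  allDownstreamStarts = TRUE)
  f1 <- all[all$strand == "+" & all$frame == 1, ]
  expect_equal(nrow(f1), 2L)
  expect_equal(sort(f1$start), c(4L, 10L))
  expect_equal(unique(f1$end_no_stop), 15L)
  one <- scanOrfs(g, std, minAa = 1, mode = "atg_initiated")
  expect_equal(one[one$strand == "+" & one$frame == 1, "start"], 4L)
})

test_that("frame labels follow the positional formula on both strands", {
  expect_equal(frameOf(1, "+", 300), 1L)
  expect_equal(frameOf(4, "+", 300), 1L)
  expect_equal(frameOf(5, "+", 300), 2L)
  expect_equal(frameOf(300, "-", 300), -1L)
  expect_error(frameOf(0, "+", 300), "out of range")
  # positions differing by 1 mod 3 land in different frame classes
  expect_equal((frameOf(11557, "+", 16569) - frameOf(11115, "+", 16569)) %% 3,
               (11557 - 11115) %% 3)
})

test_that("a stop-free frame cycle is reported once, wrapping the origin", {
  # frame 1 all-Lys circle; frames 2/3 contain stops
  g <- circularGenome(strrep("AAA", 20))
  o <- scanOrfs(g, std, minAa = 1)
  f1 <- o[o$frame == 1 & o$strand == "+", ]
  expect_equal(nrow(f1), 1L)
  expect_true(f1$wraps_origin)
  expect_false(f1$has_stop)
  expect_equal(f1$aa_length, 20L)
  expect_equal(f1$start, 1L)
})

test_that("interval exports round-trip through GRanges, BED and GFF3", {
  g <- circularGenome("TAAATGGCATAGCCCTAAATGAAATAGGGG", topology = "linear")
  o <- scanOrfs(g, std, minAa = 1)
  gr <- orfsAsGRanges(o, length(g))
  expect_true(all(o$orf_id %in% gr$orf_id))
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeOrfBed(o, bed, length(g))
  writeOrfGff3(o, gff, length(g))
  writeOrfFasta(o, fa)
  reread <- rtracklayer::import(bed)
  expect_equal(length(reread), length(gr))
  peps <- Biostrings::readAAStringSet(fa)
  expect_setequal(as.character(peps), o$aa_sequence)
})
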