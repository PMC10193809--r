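## Six-frame ORF enumeration on circular (or linear) genomes.
##
## A circular genome of length L divisible by 3 has three disjoint codon
## cycles per strand (the classic frames); when L is not divisible by 3 the
## codon walk (step 3 mod L) visits every position, so the strand has a
## single cycle of L codons. Stop-to-stop runs are maximal stop-free codon
## stretches within a cycle; a wholly stop-free cycle yields one record
## flagged wraps_origin with its canonical start at the lowest reference
## position.

#' Reading-frame label of a position
#'
#' Plus strand: \code{((start - 1) mod 3) + 1}, i.e. positions 1, 4, 7 ...
#' are frame 1. Minus strand: \code{-(((L - start) mod 3) + 1)}, which is
#' the same rule applied in reverse-complement coordinates. Frame labels are
#' a bookkeeping convention; relationships between ORFs and host genes are
#' expressed convention-free via [frameOffset()].
#'
#' @param start 1-based reference position of the first coding base.
#' @param strand \code{"+"} or \code{"-"}.
#' @param genomeLength Genome length in nt.
#' @return Integer in \{1, 2, 3\} (plus) or \{-1, -2, -3\} (minus).
#' @export
frameOf <- function(start, strand, genomeLength) {
  if (any(start < 1L | start > genomeLength)) {
    stop("start out of range 1..genomeLength", call. = FALSE)
  }
  ifelse(strand == "+",
         ((start - 1L) %% 3L) + 1L,
         -(((genomeLength - start) %% 3L) + 1L))
}

## Enumerate codon cycles of one strand-local sequence. Returns a list of
## runs: list(start0 = 0-based nt start, len = codons, aa, hasStop, codons).
.strandRuns <- function(S, circular, code) {
  L <- nchar(S)
  runs <- list()
  emit <- function(start0, idx, aa, hasStop) {
    runs[[length(runs) + 1L]] <<- list(start0 = start0, len = length(idx),
                                       aa = aa, hasStop = hasStop)
  }
  if (!circular) {
    for (f in 0:2) {
      if (L - f < 3L) next
      starts0 <- seq.int(f, L - 3L, by = 3L)
      codons <- substring(S, starts0 + 1L, starts0 + 3L)
      aa <- .codonsToAa(codons, code)
      stops <- aa == "*"
      bounds <- c(0L, which(stops), length(codons) + 1L)
      for (b in seq_len(length(bounds) - 1L)) {
        from <- bounds[b] + 1L
        to <- bounds[b + 1L] - 1L
        if (to < from) next
        emit(starts0[from], from:to, paste(aa[from:to], collapse = ""),
             hasStop = bounds[b + 1L] <= length(codons))
      }
    }
  } else {
    SS <- paste0(S, S)
    g <- if (L %% 3L == 0L) 3L else 1L
    ncod <- L %/% g
    for (r in seq_len(g) - 1L) {
      starts0 <- (r + 3L * (seq_len(ncod) - 1L)) %% L
      codons <- substring(SS, starts0 + 1L, starts0 + 3L)
      aa <- .codonsToAa(codons, code)
      stops <- aa == "*"
      if (!any(stops)) {
        k0 <- which.min(starts0)
        idx <- ((k0 - 1L + seq_len(ncod) - 1L) %% ncod) + 1L
        emit(starts0[k0], idx, paste(aa[idx], collapse = ""), hasStop = FALSE)
      } else {
        iStops <- which(stops)
        nS <- length(iStops)
        for (si in seq_len(nS)) {
          from <- iStops[si] + 1L
          to <- (if (si < nS) iStops[si + 1L] else iStops[1L] + ncod) - 1L
          if (to < from) next
          idx <- ((from:to - 1L) %% ncod) + 1L
          emit(starts0[idx[1L]], idx, paste(aa[idx], collapse = ""),
               hasStop = TRUE)
        }
      }
    }
  }
  runs
}

#' Scan a genome for open reading frames in all six frames
#'
#' Two discovery modes are provided. \code{"stop_to_stop"} emits every
#' maximal stop-free codon run of at least \code{minAa} codons (peptides may
#' begin with any residue; this is the mode that surfaces unannotated
#' mitochondrial ORF catalogues). \code{"atg_initiated"} emits, within each
#' stop-to-stop run, the ORF from the 5'-most start codon to the run's stop;
#' with \code{allDownstreamStarts} every in-frame start codon yields a
#' record, which is how a downstream alternative initiation codon inside an
#' annotated gene is surfaced.
#'
#' Coordinates are 1-based reference positions of the first and last coding
#' base (the stop codon is excluded). Minus-strand records report
#' \code{start > end_no_stop}, the conventional dialect for antisense ORFs
#' on an annotated plus-strand reference.
#'
#' @param genome A [CircularGenome-class].
#' @param code A [GeneticCode-class].
#' @param minAa Minimum peptide length in amino acids (stop excluded).
#' @param mode \code{"stop_to_stop"} or \code{"atg_initiated"}.
#' @param strands Strands to scan.
#' @param startCodons Start-codon set for ATG mode; defaults to
#'   \code{"ATG"} (use \code{startCodons(code)} to scan with the code's full
#'   initiator set).
#' @param allDownstreamStarts Emit one record per in-frame start codon
#'   rather than only the 5'-most.
#' @return A data.frame with one row per ORF: \code{orf_id},
#'   \code{genome_id}, \code{strand}, \code{frame}, \code{start},
#'   \code{end_no_stop}, \code{has_stop}, \code{wraps_origin}, \code{mode},
#'   \code{aa_sequence}, \code{aa_length}, \code{nt_length_with_stop}.
#' @examples
#' g <- circularGenome("TAAATGGCATAG", topology = "linear")
#' scanOrfs(g, loadGeneticCode("standard"), minAa = 1)
#' @export
scanOrfs <- function(genome, code, minAa = 20L,
                     mode = c("stop_to_stop", "atg_initiated"),
                     strands = c("+", "-"),
                     startCodons = "ATG",
                     allDownstreamStarts = FALSE) {
  stopifnot(is(genome, "CircularGenome"), is(code, "GeneticCode"))
  mode <- match.arg(mode)
  if (minAa < 1L) stop("minAa must be >= 1", call. = FALSE)
  L <- length(genome)
  if (L < 3L) stop("genome shorter than 3 nt", call. = FALSE)
  circular <- genomeTopology(genome) == "circular"
  out <- list()
  for (strand in strands) {
    S <- if (strand == "+") genomeSequence(genome) else
      revComp(genomeSequence(genome))
    SS <- if (circular) paste0(S, S) else S
    runs <- .strandRuns(S, circular, code)
    for (run in runs) {
      if (mode == "stop_to_stop") {
        cand <- list(list(offset = 0L))
      } else {
        starts0 <- (run$start0 + 3L * (seq_len(run$len) - 1L)) %% L
        codons <- substring(SS, starts0 + 1L, starts0 + 3L)
        hits <- which(codons %in% startCodons)
        if (!allDownstreamStarts && length(hits)) hits <- hits[1L]
        cand <- lapply(hits, function(j) list(offset = j - 1L))
      }
      for (cc in cand) {
        len <- run$len - cc$offset
        if (len < minAa) next
        start0 <- (run$start0 + 3L * cc$offset) %% L
        aa <- substring(run$aa, cc$offset + 1L, run$len)
        end0 <- (start0 + 3L * len - 1L) %% L
        localStart <- start0 + 1L
        localEnd <- end0 + 1L
        if (strand == "+") {
          refStart <- localStart; refEnd <- localEnd
        } else {
          refStart <- L - localStart + 1L; refEnd <- L - localEnd + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          genome_id = genomeId(genome),
          strand = strand,
          frame = frameOf(refStart, strand, L),
          start = refStart, end_no_stop = refEnd,
          has_stop = run$hasStop,
          wraps_origin = circular &&
            (!run$hasStop || (start0 + 3L * len) > L),
          mode = mode,
          aa_sequence = aa, aa_length = len,
          nt_length_with_stop = 3L * len + if (run$hasStop) 3L else 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    res <- data.frame(genome_id = character(), strand = character(),
                      frame = integer(), start = integer(),
                      end_no_stop = integer(), has_stop = logical(),
                      wraps_origin = logical(), mode = character(),
                      aa_sequence = character(), aa_length = integer(),
                      nt_length_with_stop = integer(),
                      stringsAsFactors = FALSE)
    res$orf_id <- character()
    return(res[, c("orf_id", setdiff(names(res), "orf_id"))])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$strand, res$frame, res$start, res$aa_length), ,
             drop = FALSE]
  rownames(res) <- NULL
  res$orf_id <- sprintf("%s_orf%04d", res$genome_id, seq_len(nrow(res)))
  res[, c("orf_id", setdiff(names(res), "orf_id"))]
}

#' Convert ORF records to GRanges
#'
#' ORFs crossing the origin are split into two ranges sharing the same
#' \code{orf_id} (standard practice for circular molecules in linear
#' interval formats).
#'
#' @param orfs ORF data.frame from [scanOrfs()].
#' @param genomeLength Genome length in nt.
#' @return A [GenomicRanges::GRanges] with an \code{orf_id} column.
#' @export
orfsAsGRanges <- function(orfs, genomeLength) {
  if (!nrow(orfs)) {
    return(GenomicRanges::GRanges())
  }
  rows <- list()
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    lo <- min(o$start, o$end_no_stop)
    hi <- max(o$start, o$end_no_stop)
    if (!o$wraps_origin) {
      rows[[length(rows) + 1L]] <- c(lo, hi, i)
    } else {
      rows[[length(rows) + 1L]] <- c(hi, genomeLength, i)
      rows[[length(rows) + 1L]] <- c(1L, lo, i)
    }
  }
  m <- do.call(rbind, rows)
  idx <- m[, 3L]
  GenomicRanges::GRanges(
    seqnames = orfs$genome_id[idx],
    ranges = IRanges::IRanges(start = m[, 1L], end = m[, 2L]),
    strand = orfs$strand[idx],
    orf_id = orfs$orf_id[idx],
    aa_length = orfs$aa_length[idx])
}

#' Write ORF peptides as FASTA
#'
#' @param orfs ORF data.frame from [scanOrfs()].
#' @param path Output path.
#' @export
writeOrfFasta <- function(orfs, path) {
  set <- Biostrings::AAStringSet(stats::setNames(orfs$aa_sequence,
                                                 orfs$orf_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write ORF records as BED or GFF3
#'
#' BED output is 0-based half-open with a strand column; GFF3 is 1-based
#' closed. Origin-crossing ORFs are written as two intervals sharing an ID.
#'
#' @param orfs ORF data.frame from [scanOrfs()].
#' @param path Output path.
#' @param genomeLength Genome length in nt.
#' @export
writeOrfBed <- function(orfs, path, genomeLength) {
  gr <- orfsAsGRanges(orfs, genomeLength)
  names(gr) <- gr$orf_id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeOrfBed
#' @export
writeOrfGff3 <- function(orfs, path, genomeLength) {
  gr <- orfsAsGRanges(orfs, genomeLength)
  if (length(gr)) {
    gr$type <- "ORF"
    gr$ID <- gr$orf_id
  }
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
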