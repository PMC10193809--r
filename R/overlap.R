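## Classification of ORFs against reference annotations.

## Overlap length of two circular arcs given as 0-based (start, len) on a
## circle of length L. Two shifted copies cover every wrap configuration.
.circOverlap <- function(s1, l1, s2, l2, L) {
  lin <- function(a1, b1, a2, b2) max(0L, min(b1, b2) - max(a1, a2))
  ov <- lin(s1, s1 + l1, s2, s2 + l2) +
    lin(s1, s1 + l1, s2 + L, s2 + L + l2) +
    lin(s1 + L, s1 + L + l1, s2, s2 + l2)
  min(ov, l1, l2)
}

## Ascending-coordinate arc (0-based start, length) covered by an ORF's
## coding nucleotides.
.orfArc <- function(orf) {
  lo <- if (orf$strand == "+") orf$start else orf$end_no_stop
  list(s = lo - 1L, l = 3L * orf$aa_length)
}

.annArc <- function(ann, L) {
  len <- ifelse(ann$wraps, L - ann$start + 1L + ann$end,
                ann$end - ann$start + 1L)
  list(s = ann$start - 1L, l = len)
}

#' Frame offset between an ORF and its host gene
#'
#' The offset is taken along the shared strand's 5'-to-3' axis, so it is
#' independent of any global frame-labelling convention:
#' \code{(orfStart - hostStart) mod 3} on the plus strand and
#' \code{(hostStart - orfStart) mod 3} on the minus strand (reference
#' coordinates of the 5' coding base in both cases). An offset of 1 or 2 is
#' a sense frameshift; 0 means the same reading frame.
#'
#' @param orfStart 1-based reference position of the ORF's 5' coding base.
#' @param hostStart 1-based reference position of the host's 5' coding base.
#' @param strand Shared strand, \code{"+"} or \code{"-"}.
#' @param sameStrand Must be TRUE; the offset is undefined across strands.
#' @return Integer offset in \{0, 1, 2\}.
#' @export
frameOffset <- function(orfStart, hostStart, strand = "+", sameStrand = TRUE) {
  if (!isTRUE(sameStrand)) {
    stop("frame offset is undefined across strands; classify as antisense",
         call. = FALSE)
  }
  if (strand == "+") (orfStart - hostStart) %% 3L
  else (hostStart - orfStart) %% 3L
}

.hostEnds <- function(ann) {
  if (ann$strand == "+") list(h5 = ann$start, h3 = ann$end)
  else list(h5 = ann$end, h3 = ann$start)
}

#' Classify ORFs against reference annotations
#'
#' Each ORF is assigned the feature with maximal nucleotide overlap
#' (computed on circular coordinates) as its host. Categories:
#' \describe{
#'   \item{matches_reference}{coordinates, strand and frame coincide with a
#'     protein-coding feature (the annotated 3' end may or may not include
#'     the stop codon; both conventions are accepted).}
#'   \item{sense_frameshift}{same strand as a protein-coding host but not
#'     the reference record itself; \code{frame_offset} gives the shift
#'     (0 for a same-frame nested ORF such as a downstream-start
#'     truncation).}
#'   \item{antisense}{opposite strand to a protein-coding host; frame is
#'     ignored.}
#'   \item{within_rRNA, within_tRNA}{hosted by an RNA gene (either strand).}
#'   \item{intergenic}{no feature overlap, or hosted by the D-loop (the
#'     control region is non-coding; its name is still recorded as
#'     \code{host_feature}).}
#'   \item{multi_feature}{an exact tie in nucleotide overlap between two or
#'     more features; all hosts are listed comma-separated.}
#' }
#' Micropeptide-type annotations do not compete for host assignment; they
#' are matched by [filterUnannotated()].
#'
#' @param orfs ORF data.frame from [scanOrfs()].
#' @param annotations Annotation data.frame from [geneAnnotations()] or
#'   [readAnnotationsGff3()].
#' @param genomeLength Genome length in nt.
#' @return The input with columns \code{category}, \code{host_feature},
#'   \code{frame_offset} and \code{overlap_nt} appended.
#' @export
classifyOrfs <- function(orfs, annotations, genomeLength) {
  ann <- annotations[annotations$feature_type != "micropeptide", ,
                     drop = FALSE]
  if (!"wraps" %in% names(ann)) ann$wraps <- FALSE
  n <- nrow(orfs)
  category <- character(n)
  host <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  ovl <- integer(n)
  arcs <- lapply(seq_len(nrow(ann)),
                 function(j) .annArc(ann[j, ], genomeLength))
  for (i in seq_len(n)) {
    orf <- orfs[i, ]
    oa <- .orfArc(orf)
    ov <- if (nrow(ann)) vapply(arcs, function(a)
      as.numeric(.circOverlap(oa$s, oa$l, a$s, a$l, genomeLength)),
      numeric(1L)) else numeric(0)
    if (!length(ov) || max(ov) == 0) {
      category[i] <- "intergenic"
      next
    }
    best <- which(ov == max(ov))
    ovl[i] <- as.integer(max(ov))
    if (length(best) > 1L) {
      category[i] <- "multi_feature"
      host[i] <- paste(ann$name[best], collapse = ",")
      next
    }
    h <- ann[best, ]
    host[i] <- h$name
    if (h$feature_type == "rRNA") {
      category[i] <- "within_rRNA"
    } else if (h$feature_type == "tRNA") {
      category[i] <- "within_tRNA"
    } else if (h$feature_type == "D_loop") {
      category[i] <- "intergenic"
    } else {  # protein_coding
      if (orf$strand != h$strand) {
        category[i] <- "antisense"
      } else {
        he <- .hostEnds(h)
        off <- frameOffset(orf$start, he$h5, strand = orf$strand)
        offset[i] <- off
        endsMatch <- if (orf$strand == "+") {
          orf$end_no_stop %in% c(he$h3, he$h3 - 3L)
        } else {
          orf$end_no_stop %in% c(he$h3, he$h3 + 3L)
        }
        if (off == 0L && orf$start == he$h5 && endsMatch) {
          category[i] <- "matches_reference"
        } else {
          category[i] <- "sense_frameshift"
        }
      }
    }
  }
  orfs$category <- category
  orfs$host_feature <- host
  orfs$frame_offset <- offset
  orfs$overlap_nt <- ovl
  orfs
}

#' Drop reference-matching and known ORFs from a scan
#'
#' Removes records classified \code{matches_reference} and records equal to
#' a known ORF, by exact peptide string or by coordinate identity (whichever
#' the known-ORF table provides). Everything else is retained, including
#' ORFs inside rRNA and tRNA genes: literature micropeptides live inside
#' structural RNA genes, so RNA residency is not grounds for removal.
#'
#' @param orfs ORF data.frame from [scanOrfs()].
#' @param annotations Annotation data.frame.
#' @param genomeLength Genome length in nt.
#' @param knownOrfs Optional data.frame (see [readKnownOrfs()]) with
#'   \code{name} and any of \code{aa_sequence}, \code{start}, \code{end},
#'   \code{strand}.
#' @return The retained ORFs, classification columns included.
#' @export
filterUnannotated <- function(orfs, annotations, genomeLength,
                              knownOrfs = NULL) {
  cls <- classifyOrfs(orfs, annotations, genomeLength)
  drop <- cls$category == "matches_reference"
  if (!is.null(knownOrfs) && nrow(knownOrfs)) {
    seqs <- knownOrfs$aa_sequence
    seqs <- seqs[!is.na(seqs)]
    if (length(seqs)) drop <- drop | cls$aa_sequence %in% seqs
    coords <- knownOrfs[!is.na(knownOrfs$start) & !is.na(knownOrfs$end), ,
                        drop = FALSE]
    if (nrow(coords)) {
      key <- paste(cls$start, cls$end_no_stop, cls$strand)
      kk <- paste(coords$start, coords$end,
                  ifelse(is.na(coords$strand), "+", coords$strand))
      drop <- drop | key %in% kk
    }
  }
  cls[!drop, , drop = FALSE]
}
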