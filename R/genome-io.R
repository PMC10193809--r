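## FASTA / GFF3 input and the annotation table.

#' Construct a CircularGenome from a DNA string
#'
#' @param sequence DNA string (U converted to T; N allowed as a placeholder).
#' @param id Sequence identifier.
#' @param topology \code{"circular"} (default) or \code{"linear"}.
#' @return A [CircularGenome-class] object.
#' @export
circularGenome <- function(sequence, id = "genome", topology = "circular") {
  new("CircularGenome", id = id, sequence = .normDna(sequence),
      topology = topology)
}

#' Read a single-record genome FASTA
#'
#' Multi-record FASTA files are rejected: the scanner works on one circular
#' (or linear) molecule at a time.
#'
#' @param path Path to a FASTA file with exactly one record.
#' @param topology Genome topology, \code{"circular"} by default.
#' @return A [CircularGenome-class] object.
#' @export
readCircularGenome <- function(path, topology = "circular") {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop(sprintf("expected a single-record FASTA, found %d records in '%s'",
                 length(set), path), call. = FALSE)
  }
  circularGenome(as.character(set[[1L]]),
                 id = sub("\\s.*$", "", names(set)[1L]),
                 topology = topology)
}

.FEATURE_TYPES <- c("protein_coding", "rRNA", "tRNA", "D_loop", "micropeptide")

#' Build an annotation table
#'
#' Reference features are held as a plain data.frame with 1-based closed
#' coordinates (\code{start <= end} unless the feature wraps the origin, in
#' which case \code{wraps} is set).
#'
#' @param name Feature names, unique within a feature type.
#' @param feature_type One of \code{protein_coding}, \code{rRNA},
#'   \code{tRNA}, \code{D_loop}, \code{micropeptide}.
#' @param start,end 1-based closed reference coordinates.
#' @param strand \code{"+"} or \code{"-"}.
#' @param wraps Does the feature cross the origin?
#' @return A data.frame of annotations.
#' @export
geneAnnotations <- function(name, feature_type, start, end, strand = "+",
                            wraps = FALSE) {
  n <- length(name)
  ann <- data.frame(name = as.character(name),
                    feature_type = as.character(feature_type),
                    start = as.integer(start), end = as.integer(end),
                    strand = rep_len(as.character(strand), n),
                    wraps = rep_len(as.logical(wraps), n),
                    stringsAsFactors = FALSE)
  bad <- !ann$feature_type %in% .FEATURE_TYPES
  if (any(bad)) {
    stop("unknown feature_type: ",
         paste(unique(ann$feature_type[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(ann$start > ann$end & !ann$wraps)) {
    stop("start > end for a non-wrapping feature", call. = FALSE)
  }
  if (anyDuplicated(paste(ann$feature_type, ann$name))) {
    stop("feature names must be unique within a feature type", call. = FALSE)
  }
  ann
}

## Sequence-ontology-ish type mapping used on GFF3 import.
.soTypeMap <- function(types) {
  out <- rep(NA_character_, length(types))
  out[types %in% c("gene", "CDS", "mRNA", "protein_coding_gene")] <- "protein_coding"
  out[types %in% c("rRNA", "rRNA_gene")] <- "rRNA"
  out[types %in% c("tRNA", "tRNA_gene")] <- "tRNA"
  out[types %in% c("D_loop", "D-loop", "displacement_loop")] <- "D_loop"
  out[types %in% c("micropeptide", "sORF", "small_ORF")] <- "micropeptide"
  out
}

#' Read reference annotations from GFF3
#'
#' Standard SO feature types are mapped onto the internal vocabulary
#' (gene/CDS to protein_coding, rRNA, tRNA, D_loop, micropeptide); rows of
#' unrecognised type are dropped. When both a gene and its CDS are present
#' the CDS is preferred.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame as produced by [geneAnnotations()].
#' @export
readAnnotationsGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- .soTypeMap(as.character(gr$type))
  keep <- !is.na(type)
  gr <- gr[keep]
  type <- type[keep]
  nm <- gr$Name
  if (is.null(nm)) nm <- gr$ID
  nm[is.na(nm) | !nzchar(nm)] <- gr$ID[is.na(nm) | !nzchar(nm)]
  ann <- geneAnnotations(name = as.character(nm), feature_type = type,
                         start = GenomicRanges::start(gr),
                         end = GenomicRanges::end(gr),
                         strand = as.character(GenomicRanges::strand(gr)))
  ## keep CDS over gene when both carry the same name
  dup <- duplicated(paste(ann$feature_type, ann$name))
  ann[!dup, , drop = FALSE]
}

#' Read a known-micropeptide sidecar table
#'
#' A user-editable TSV listing ORFs that are annotated in the literature but
#' absent from standard GFF3 annotations (e.g. Humanin, SHLP1-6, MOTS-c,
#' gau, SHMOOSE). Columns: \code{name}, and optionally \code{aa_sequence},
#' \code{start}, \code{end}, \code{strand}; empty cells mean unknown.
#'
#' @param path Path to the TSV.
#' @return A data.frame with one row per known ORF.
#' @export
readKnownOrfs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  if (!"name" %in% names(tab)) {
    stop("known-ORF table needs a 'name' column", call. = FALSE)
  }
  for (col in c("aa_sequence", "start", "end", "strand")) {
    if (!col %in% names(tab)) tab[[col]] <- NA
  }
  tab
}
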