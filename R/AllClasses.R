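#' @import methods
NULL

#' GeneticCode: a 64-codon translation table
#'
#' Holds a total mapping from the 64 DNA triplets to one-letter amino acids
#' (with \code{"*"} for stop), together with explicit start- and stop-codon
#' sets. The internal alphabet is DNA (T, not U); RNA input is converted on
#' read by the constructors.
#'
#' @slot name Identifier of the code (e.g. \code{"vertebrate_mito_modified"}).
#' @slot codonToAa Named character vector of length 64; names are the DNA
#'   triplets, values are one-letter amino acids or \code{"*"}.
#' @slot startCodons Character vector of initiator triplets; non-empty and
#'   disjoint from the stop set.
#' @slot stopCodons Character vector equal to the set of triplets mapped to
#'   \code{"*"}.
#'
#' @seealso [loadGeneticCode()], [translateCds()]
#' @export
setClass("GeneticCode",
  representation(
    name = "character",
    codonToAa = "character",
    startCodons = "character",
    stopCodons = "character"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character()
  all64 <- sort(as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0
  )))
  if (length(object@codonToAa) != 64L ||
      !identical(sort(names(object@codonToAa)), all64)) {
    msg <- c(msg, "codonToAa must have exactly the 64 DNA triplets as names")
  }
  stops <- sort(names(object@codonToAa)[object@codonToAa == "*"])
  if (!identical(sort(object@stopCodons), stops)) {
    msg <- c(msg, "stopCodons must equal the set of triplets mapped to '*'")
  }
  if (length(object@startCodons) == 0L) {
    msg <- c(msg, "startCodons must be non-empty")
  }
  if (any(object@startCodons %in% object@stopCodons)) {
    msg <- c(msg, "startCodons must be disjoint from stopCodons")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode:", object@name, "\n")
  cat("  stop codons: ", paste(sort(object@stopCodons), collapse = ", "), "\n")
  cat("  start codons:", paste(sort(object@startCodons), collapse = ", "), "\n")
  diffs <- names(object@codonToAa)[
    object@codonToAa != Biostrings::GENETIC_CODE[names(object@codonToAa)]
  ]
  if (length(diffs)) {
    cat("  differs from the standard code at:",
        paste(sort(diffs), collapse = ", "), "\n")
  }
  invisible(object)
})

#' CircularGenome: a (possibly circular) nucleotide sequence
#'
#' @slot id Sequence identifier.
#' @slot sequence Upper-case DNA string.
#' @slot topology Either \code{"circular"} or \code{"linear"}.
#'
#' @seealso [circularGenome()], [readCircularGenome()], [scanOrfs()]
#' @export
setClass("CircularGenome",
  representation(
    id = "character",
    sequence = "character",
    topology = "character"
  )
)

setValidity("CircularGenome", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || !nzchar(object@sequence)) {
    msg <- c(msg, "sequence must be a single non-empty string")
  }
  if (!object@topology %in% c("circular", "linear")) {
    msg <- c(msg, "topology must be 'circular' or 'linear'")
  }
  bad <- gsub("[ACGTN]", "", object@sequence)
  if (nzchar(bad)) {
    msg <- c(msg, sprintf("sequence contains invalid characters: '%s'",
                          substr(bad, 1L, 10L)))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CircularGenome", function(object) {
  cat(sprintf("CircularGenome '%s': %d nt, %s\n",
              object@id, nchar(object@sequence), object@topology))
  invisible(object)
})

#' @describeIn CircularGenome-class Genome length in nucleotides.
#' @param x A \code{CircularGenome}.
#' @export
setMethod("length", "CircularGenome", function(x) nchar(x@sequence))

#' Accessors for CircularGenome
#'
#' @param x A [CircularGenome-class] object.
#' @return \code{genomeSequence} returns the DNA string, \code{genomeId} the
#'   identifier, \code{genomeTopology} \code{"circular"} or \code{"linear"}.
#' @export
genomeSequence <- function(x) x@sequence

#' @rdname genomeSequence
#' @export
genomeId <- function(x) x@id

#' @rdname genomeSequence
#' @export
genomeTopology <- function(x) x@topology

#' Accessors for GeneticCode
#'
#' @param x A [GeneticCode-class] object.
#' @return \code{codonTable} returns the named 64-codon vector,
#'   \code{startCodons}/\code{stopCodons} the respective triplet sets,
#'   \code{codeName} the identifier.
#' @export
codonTable <- function(x) x@codonToAa

#' @rdname codonTable
#' @export
startCodons <- function(x) x@startCodons

#' @rdname codonTable
#' @export
stopCodons <- function(x) x@stopCodons

#' @rdname codonTable
#' @export
codeName <- function(x) x@name
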