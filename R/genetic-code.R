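## Codon translation tables and strand-aware translation primitives.

.normDna <- function(nt) {
  nt <- toupper(nt)
  chartr("U", "T", nt)
}

.checkDna <- function(nt, lenient = FALSE) {
  ok <- if (lenient) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(ok, nt)
  if (bad > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(nt, bad, bad), bad), call. = FALSE)
  }
  invisible(nt)
}

#' Load a named genetic code
#'
#' Three codes are built in. \code{"standard"} is the universal code.
#' \code{"vertebrate_mito"} is the vertebrate mitochondrial code (NCBI
#' transl_table 2: TGA is Trp, ATA is Met, AGA/AGG are stops).
#' \code{"vertebrate_mito_modified"} is transl_table 2 with AGA and AGG read
#' as arginine, so the stop set is exactly TAA and TAG; this reflects the
#' view that human mitochondria do not use AGA/AGG for termination.
#'
#' Start sets default to ATG for the standard code and \{ATG, ATA, ATT\} for
#' the mitochondrial codes; \code{atgOnly = TRUE} restricts any code to ATG
#' (the convention of ATG-anchored ORF catalogues such as OpenProt).
#'
#' @param name One of \code{"standard"}, \code{"vertebrate_mito"},
#'   \code{"vertebrate_mito_modified"}.
#' @param atgOnly Restrict the start-codon set to ATG.
#' @return A [GeneticCode-class] object.
#' @examples
#' code <- loadGeneticCode("vertebrate_mito_modified")
#' codonTable(code)[["AGA"]]  # "R"
#' stopCodons(code)           # TAA, TAG
#' @export
loadGeneticCode <- function(name = c("standard", "vertebrate_mito",
                                     "vertebrate_mito_modified"),
                            atgOnly = FALSE) {
  valid <- c("standard", "vertebrate_mito", "vertebrate_mito_modified")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop("unknown genetic code; valid names: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  if (name == "standard") {
    tab <- Biostrings::GENETIC_CODE
    starts <- "ATG"
  } else {
    tab <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
    starts <- c("ATG", "ATA", "ATT")
    if (name == "vertebrate_mito_modified") {
      tab[c("AGA", "AGG")] <- "R"
    }
  }
  tab <- stats::setNames(as.character(tab), names(tab))
  if (atgOnly) starts <- "ATG"
  new("GeneticCode",
      name = name,
      codonToAa = tab,
      startCodons = starts,
      stopCodons = names(tab)[tab == "*"])
}

#' Load a user-supplied genetic code from a two-column table
#'
#' The file must be whitespace- or tab-separated with one row per codon:
#' codon then one-letter amino acid (\code{"*"} for stop). All 64 triplets
#' must be present. RNA codons (U) are accepted and converted to DNA.
#'
#' @param path Path to the table.
#' @param name Identifier for the resulting code.
#' @param startCodons Initiator triplets (default ATG).
#' @return A [GeneticCode-class] object.
#' @export
readGeneticCode <- function(path, name = "custom", startCodons = "ATG") {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("codon", "aa"))
  codons <- .normDna(tab$codon)
  new("GeneticCode",
      name = name,
      codonToAa = stats::setNames(tab$aa, codons),
      startCodons = .normDna(startCodons),
      stopCodons = codons[tab$aa == "*"])
}

## Fast internal path: translate a character vector of codons; no stop
## handling, 'X' for any triplet containing an ambiguity code.
.codonsToAa <- function(codons, code) {
  aa <- unname(code@codonToAa[codons])
  aa[is.na(aa)] <- "X"
  aa
}

.splitCodons <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return(character())
  substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a coding nucleotide string
#'
#' Translates consecutive non-overlapping triplets from position 1 and halts
#' before the first stop codon (the stop is not emitted). The number of
#' nucleotides consumed (a multiple of 3; includes no stop) is returned
#' alongside the peptide so callers can implement their own internal-stop
#' policy.
#'
#' @param nt Nucleotide string over A/C/G/T (U accepted and converted).
#' @param code A [GeneticCode-class] object.
#' @param trimIncomplete Drop a trailing 1-2 nt remainder instead of
#'   erroring.
#' @param lenient Translate any triplet containing N as \code{"X"} instead
#'   of erroring (the human mtDNA reference contains one placeholder
#'   position).
#' @return A list with elements \code{aa} (peptide, no stop symbol) and
#'   \code{ntConsumed}.
#' @examples
#' translateCds("ATGAGATAA", loadGeneticCode("vertebrate_mito_modified"))
#' @export
translateCds <- function(nt, code, trimIncomplete = FALSE, lenient = FALSE) {
  stopifnot(is(code, "GeneticCode"))
  nt <- .normDna(nt)
  .checkDna(nt, lenient = lenient)
  rem <- nchar(nt) %% 3L
  if (rem != 0L && !trimIncomplete) {
    stop(sprintf("sequence length %d is not a multiple of 3 (set trimIncomplete)",
                 nchar(nt)), call. = FALSE)
  }
  codons <- .splitCodons(nt)
  aa <- .codonsToAa(codons, code)
  stopAt <- match("*", aa)
  if (!is.na(stopAt)) aa <- aa[seq_len(stopAt - 1L)]
  list(aa = paste(aa, collapse = ""), ntConsumed = 3L * length(aa))
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement (involutive). N is preserved.
#'
#' @param nt Nucleotide string over A/C/G/T/N.
#' @return The reverse-complemented string.
#' @examples
#' revComp("ATGC")  # "GCAT"
#' @export
revComp <- function(nt) {
  nt <- .normDna(nt)
  .checkDna(nt, lenient = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}
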