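## In-silico tryptic digestion for MS query preparation.

#' Digestion parameter set
#'
#' Defaults mirror common proteogenomics search conditions: up to 2 missed
#' cleavages, a minimum peptide length of 7 residues and a 400-6000 Da mass
#' window, with the proline rule on (trypsin does not cleave K/R-P) and
#' monoisotopic masses (the MS search convention).
#'
#' @param maxMiscleavages Maximum missed cleavages (0-5).
#' @param minLen Minimum peptide length in residues.
#' @param massMin,massMax Mass window in Da.
#' @param prolineRule Suppress cleavage before proline.
#' @param massKind \code{"monoisotopic"} or \code{"average"}.
#' @return A list of class \code{"DigestParams"}.
#' @export
digestParams <- function(maxMiscleavages = 2L, minLen = 7L,
                         massMin = 400, massMax = 6000,
                         prolineRule = TRUE,
                         massKind = c("monoisotopic", "average")) {
  massKind <- match.arg(massKind)
  if (maxMiscleavages < 0L || maxMiscleavages > 5L) {
    stop("maxMiscleavages must be in 0..5", call. = FALSE)
  }
  if (minLen < 1L) stop("minLen must be >= 1", call. = FALSE)
  if (!(massMin < massMax)) stop("massMin must be < massMax", call. = FALSE)
  structure(list(maxMiscleavages = as.integer(maxMiscleavages),
                 minLen = as.integer(minLen),
                 massMin = massMin, massMax = massMax,
                 prolineRule = prolineRule, massKind = massKind),
            class = "DigestParams")
}

#' Tryptic cleavage sites
#'
#' Positions after which trypsin cuts: every K or R except a terminal one,
#' and, when \code{prolineRule} is on, except those followed by proline.
#'
#' @param aa Amino-acid string.
#' @param prolineRule Suppress sites followed by P.
#' @return Integer vector of cleavage positions (cut is after the
#'   position), possibly empty.
#' @examples
#' cleavageSites("ARKR")  # 2, 3: the terminal R is never a site
#' @export
cleavageSites <- function(aa, prolineRule = TRUE) {
  res <- .residues(aa)
  n <- length(res)
  if (n < 2L) return(integer(0))
  pos <- which(res[-n] %in% c("K", "R"))
  if (prolineRule && length(pos)) pos <- pos[res[pos + 1L] != "P"]
  pos
}

#' In-silico tryptic digestion of a protein
#'
#' Enumerates every peptide spanning 0..\code{maxMiscleavages} consecutive
#' cleavage intervals and filters by minimum length and the mass window.
#' Output order is deterministic: by start position, then length.
#'
#' @param aa Amino-acid string of the parent protein.
#' @param params A [digestParams()] object.
#' @param parentId Identifier carried into the output.
#' @return A data.frame with \code{parent_id}, \code{aa_sequence},
#'   \code{start_in_parent} (1-based residue), \code{miscleavages} and
#'   \code{mass} (Da, in the parameter set's mass kind).
#' @export
digestProtein <- function(aa, params = digestParams(), parentId = "protein") {
  stopifnot(inherits(params, "DigestParams"))
  n <- nchar(aa)
  sites <- cleavageSites(aa, prolineRule = params$prolineRule)
  bounds <- c(0L, sites, n)  # fragment boundaries
  nf <- length(bounds) - 1L
  massFun <- if (params$massKind == "monoisotopic") monoisotopicMass
             else averageMass
  out <- list()
  for (i in seq_len(nf)) {
    for (m in 0:params$maxMiscleavages) {
      j <- i + m
      if (j > nf) break
      from <- bounds[i] + 1L
      to <- bounds[j + 1L]
      if (to - from + 1L < params$minLen) next
      pep <- substring(aa, from, to)
      mass <- massFun(pep)
      if (mass < params$massMin || mass > params$massMax) next
      out[[length(out) + 1L]] <- data.frame(
        parent_id = parentId, aa_sequence = pep,
        start_in_parent = from, miscleavages = m, mass = mass,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(parent_id = character(), aa_sequence = character(),
                      start_in_parent = integer(), miscleavages = integer(),
                      mass = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start_in_parent, nchar(res$aa_sequence)), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Digest a set of peptides (e.g. a scanned ORF catalogue)
#'
#' @param peptides Named character vector of parent protein sequences, or a
#'   peptide FASTA path.
#' @param params A [digestParams()] object.
#' @return Row-bound [digestProtein()] output for all parents.
#' @export
digestPeptides <- function(peptides, params = digestParams()) {
  if (is.character(peptides) && length(peptides) == 1L &&
      file.exists(peptides)) {
    set <- Biostrings::readAAStringSet(peptides)
    peptides <- stats::setNames(as.character(set),
                                sub("\\s.*$", "", names(set)))
  }
  if (is.null(names(peptides))) {
    names(peptides) <- sprintf("protein%03d", seq_along(peptides))
  }
  res <- lapply(names(peptides), function(id)
    digestProtein(peptides[[id]], params, parentId = id))
  do.call(rbind, res)
}

#' Write digestion output
#'
#' \code{writeDigestTsv} writes the full query table;
#' \code{writePeptideList} writes one peptide sequence per line, the input
#' format of external spectrum-matching tools.
#'
#' @param queries Output of [digestPeptides()].
#' @param path Output path.
#' @export
writeDigestTsv <- function(queries, path) {
  utils::write.table(queries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDigestTsv
#' @export
writePeptideList <- function(queries, path) {
  writeLines(unique(queries$aa_sequence), path)
  invisible(path)
}
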