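## Peptide molecular mass from residue elemental composition.
##
## Average masses use the IUPAC conventional atomic weights C 12.0107,
## H 1.00794, N 14.0067, O 15.9994, S 32.065; monoisotopic masses use the
## CODATA most-abundant-isotope masses. Fixing the atomic-weight vintage in
## code keeps the tables bit-stable across R and OS versions.

.ELEM_AVG <- c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994, S = 32.065)
.ELEM_MONO <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)

## residue (= amino acid minus water) elemental compositions, C H N O S
.RESIDUE_FORMULA <- matrix(c(
  3, 5, 1, 1, 0,   # A
  3, 5, 1, 1, 1,   # C
  4, 5, 1, 3, 0,   # D
  5, 7, 1, 3, 0,   # E
  9, 9, 1, 1, 0,   # F
  2, 3, 1, 1, 0,   # G
  6, 7, 3, 1, 0,   # H
  6, 11, 1, 1, 0,  # I
  6, 12, 2, 1, 0,  # K
  6, 11, 1, 1, 0,  # L
  5, 9, 1, 1, 1,   # M
  4, 6, 2, 2, 0,   # N
  5, 7, 1, 1, 0,   # P
  5, 8, 2, 2, 0,   # Q
  6, 12, 4, 1, 0,  # R
  3, 5, 1, 2, 0,   # S
  4, 7, 1, 2, 0,   # T
  5, 9, 1, 1, 0,   # V
  11, 10, 2, 1, 0, # W
  9, 9, 1, 2, 0    # Y
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("C", "H", "N", "O", "S")))

.RESIDUE_AVG <- drop(.RESIDUE_FORMULA %*% .ELEM_AVG[colnames(.RESIDUE_FORMULA)])
.RESIDUE_MONO <- drop(.RESIDUE_FORMULA %*% .ELEM_MONO[colnames(.RESIDUE_FORMULA)])
.WATER_AVG <- 2 * .ELEM_AVG[["H"]] + .ELEM_AVG[["O"]]
.WATER_MONO <- 2 * .ELEM_MONO[["H"]] + .ELEM_MONO[["O"]]

.residues <- function(aa) {
  res <- strsplit(aa, "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% rownames(.RESIDUE_FORMULA))
  if (length(bad)) {
    stop(sprintf("nonstandard residue '%s' at position %d",
                 res[bad[1L]], bad[1L]), call. = FALSE)
  }
  res
}

#' Peptide molecular masses
#'
#' Neutral, unmodified peptide masses: the sum of residue masses plus one
#' water. \code{averageMass} uses isotope-abundance-weighted atomic weights
#' (the mass a supplier or an SDS-PAGE-facing table reports);
#' \code{monoisotopicMass} uses most-abundant-isotope masses (the mass an
#' MS/MS search engine works with). Only the 20 standard one-letter codes
#' are accepted.
#'
#' @param aa Amino-acid string.
#' @return Mass in Da.
#' @examples
#' averageMass("G")       # 75.07
#' monoisotopicMass("G")  # 75.032
#' @export
averageMass <- function(aa) {
  sum(.RESIDUE_AVG[.residues(aa)]) + .WATER_AVG
}

#' @rdname averageMass
#' @export
monoisotopicMass <- function(aa) {
  sum(.RESIDUE_MONO[.residues(aa)]) + .WATER_MONO
}

#' Length and mass profile of peptides
#'
#' @param aa Character vector of amino-acid strings.
#' @return A data.frame with \code{aa_sequence}, \code{aa_length},
#'   \code{average_mass} and \code{monoisotopic_mass} in Da, and
#'   \code{mass_kda_1dp} (average mass in kDa rounded to one decimal, the
#'   precision of typical predicted-MW report columns).
#' @export
peptideProfile <- function(aa) {
  data.frame(
    aa_sequence = aa,
    aa_length = nchar(aa),
    average_mass = vapply(aa, averageMass, numeric(1L), USE.NAMES = FALSE),
    monoisotopic_mass = vapply(aa, monoisotopicMass, numeric(1L),
                               USE.NAMES = FALSE),
    mass_kda_1dp = round(vapply(aa, averageMass, numeric(1L),
                                USE.NAMES = FALSE) / 1000, 1L),
    stringsAsFactors = FALSE)
}
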