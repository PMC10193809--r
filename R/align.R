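## Global alignment with affine gaps, center-star progressive MSA, and
## two-tier conservation shading.

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*", "X")

.alnChars <- function(x, what = "sequence") {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% .AA_ALPHABET)
  if (length(bad)) {
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 ch[bad[1L]], bad[1L], what), call. = FALSE)
  }
  ch
}

#' Optimal global alignment of two peptides (affine gaps)
#'
#' Needleman-Wunsch-Gotoh alignment under match/mismatch scoring with
#' affine gap penalties: a gap of length k costs
#' \code{gapOpen + (k - 1) * gapExtend}. Stop symbols (\code{*}, accepted as
#' a 21st residue for ortholog sequences read through a stop) and \code{X}
#' never match anything, including themselves. Tie-breaking in the
#' traceback is deterministic: diagonal, then up (gap in \code{b}), then
#' left (gap in \code{a}).
#'
#' @param a,b Peptide strings.
#' @param match,mismatch,gapOpen,gapExtend Scoring parameters. The defaults
#'   (+1/-1/-5/-1) favour few, compact gaps, appropriate for closely
#'   related ortholog peptides.
#' @return A list with \code{a}, \code{b} (gapped strings of equal length)
#'   and \code{score}.
#' @examples
#' globalAlign("ACDEF", "ACEF")
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1,
                        gapOpen = -5, gapExtend = -1) {
  A <- .alnChars(a, "a")
  B <- .alnChars(b, "b")
  n <- length(A); m <- length(B)
  if (n == 0L || m == 0L) stop("empty peptide", call. = FALSE)
  NEG <- -1e18
  sc <- function(x, y) if (x == y && x != "*" && x != "X") match else mismatch
  ## state matrices: M diag, U gap in b (consumes a), V gap in a (consumes b)
  M <- matrix(NEG, n + 1L, m + 1L)
  U <- matrix(NEG, n + 1L, m + 1L)
  V <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) U[i + 1L, 1L] <- gapOpen + (i - 1L) * gapExtend
  for (j in seq_len(m)) V[1L, j + 1L] <- gapOpen + (j - 1L) * gapExtend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1L, j + 1L] <- sc(A[i], B[j]) +
        max(M[i, j], U[i, j], V[i, j])
      U[i + 1L, j + 1L] <- max(M[i, j + 1L] + gapOpen,
                               U[i, j + 1L] + gapExtend,
                               V[i, j + 1L] + gapOpen)
      V[i + 1L, j + 1L] <- max(M[i + 1L, j] + gapOpen,
                               U[i + 1L, j] + gapOpen,
                               V[i + 1L, j] + gapExtend)
    }
  }
  finals <- c(M[n + 1L, m + 1L], U[n + 1L, m + 1L], V[n + 1L, m + 1L])
  state <- which.max(finals + c(2e-9, 1e-9, 0))  # prefer M, then U, then V
  score <- max(finals)
  ## traceback
  outA <- character(); outB <- character()
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      outA <- c(A[i], outA); outB <- c(B[j], outB)
      prev <- c(M[i, j], U[i, j], V[i, j])
      tgt <- M[i + 1L, j + 1L] - sc(A[i], B[j])
      state <- which(abs(prev - tgt) < 1e-6)[1L]
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      outA <- c(A[i], outA); outB <- c("-", outB)
      here <- U[i + 1L, j + 1L]
      cand <- c(M[i, j + 1L] + gapOpen, U[i, j + 1L] + gapExtend,
                V[i, j + 1L] + gapOpen)
      state <- which(abs(cand - here) < 1e-6)[1L]
      i <- i - 1L
    } else {
      outA <- c("-", outA); outB <- c(B[j], outB)
      here <- V[i + 1L, j + 1L]
      cand <- c(M[i + 1L, j] + gapOpen, U[i + 1L, j] + gapOpen,
                V[i + 1L, j] + gapExtend)
      state <- which(abs(cand - here) < 1e-6)[1L]
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  list(a = paste(outA, collapse = ""), b = paste(outB, collapse = ""),
       score = score)
}

.pairIdentity <- function(a, b, ...) {
  aln <- globalAlign(a, b, ...)
  ca <- strsplit(aln$a, "")[[1L]]
  cb <- strsplit(aln$b, "")[[1L]]
  sum(ca == cb & ca != "-" & ca != "*") / length(ca)
}

#' Progressive multiple alignment of peptides (center-star)
#'
#' The center sequence is the one with the highest summed pairwise identity
#' to all others (ties broken by input order). Every other sequence is
#' aligned to the center with [globalAlign()] and the pairwise alignments
#' are merged over the center's gap profile, so a gap introduced by one
#' sequence is kept for all ("once a gap, always a gap"). Output rows keep
#' the input order.
#'
#' @param seqs Character vector of two or more peptides, optionally named.
#' @param ... Scoring parameters passed to [globalAlign()].
#' @return Named character vector of gapped sequences of equal length, with
#'   attribute \code{center} naming the center sequence.
#' @export
progressiveMsa <- function(seqs, ...) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_len(n))
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      idm[i, j] <- idm[j, i] <- .pairIdentity(seqs[[i]], seqs[[j]], ...)
    }
  }
  center <- which.max(rowSums(idm))
  others <- setdiff(seq_len(n), center)
  others <- others[order(-idm[center, others], others)]
  cChars <- .alnChars(seqs[[center]])
  lc <- length(cChars)
  ## per alignment: w[[k+1]] = chars of s aligned to gaps before center
  ## residue k+1 (k = 0..lc), z[k] = char aligned to center residue k
  W <- list(); Z <- list()
  for (o in others) {
    aln <- globalAlign(seqs[[center]], seqs[[o]], ...)
    ca <- strsplit(aln$a, "")[[1L]]
    cb <- strsplit(aln$b, "")[[1L]]
    w <- vector("list", lc + 1L)
    for (k in seq_len(lc + 1L)) w[[k]] <- character()
    z <- character(lc)
    k <- 0L
    for (col in seq_along(ca)) {
      if (ca[col] == "-") {
        w[[k + 1L]] <- c(w[[k + 1L]], cb[col])
      } else {
        k <- k + 1L
        z[k] <- cb[col]
      }
    }
    W[[as.character(o)]] <- w
    Z[[as.character(o)]] <- z
  }
  master <- integer(lc + 1L)
  for (o in others) {
    master <- pmax(master, lengths(W[[as.character(o)]]))
  }
  buildRow <- function(w, z) {
    parts <- character()
    for (k in 0:lc) {
      gapChars <- if (is.null(w)) character() else w[[k + 1L]]
      pad <- master[k + 1L] - length(gapChars)
      parts <- c(parts, gapChars, rep("-", pad),
                 if (k < lc) z[k + 1L])
    }
    paste(parts, collapse = "")
  }
  out <- character(n)
  out[center] <- buildRow(NULL, cChars)
  for (o in others) {
    out[o] <- buildRow(W[[as.character(o)]], Z[[as.character(o)]])
  }
  names(out) <- names(seqs)
  attr(out, "center") <- names(seqs)[center]
  out
}

#' Two-tier conservation shading of an alignment
#'
#' Classifies each alignment column: \code{all_conserved} when every row
#' carries the same residue with no gaps (rendered as a black background in
#' conventional figures), \code{near_conserved} when exactly n-1 of n rows
#' agree (gray background), \code{variable} otherwise. Stop symbols
#' (\code{*}) never count as conserved.
#'
#' @param msa Equal-length gapped sequences (character vector) as returned
#'   by [progressiveMsa()].
#' @return A list with \code{columns} (data.frame of \code{column_index},
#'   \code{residues}, \code{tier}) and \code{pct_all_conserved} (percent of
#'   columns fully conserved).
#' @export
conservationTiers <- function(msa) {
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  n <- nrow(mat)
  tiers <- character(ncol(mat))
  residues <- character(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    residues[j] <- paste(col, collapse = "")
    counts <- table(col[col != "-" & col != "*"])
    topN <- if (length(counts)) max(counts) else 0L
    if (topN == n) {
      tiers[j] <- "all_conserved"
    } else if (topN == n - 1L) {
      tiers[j] <- "near_conserved"
    } else {
      tiers[j] <- "variable"
    }
  }
  list(columns = data.frame(column_index = seq_len(ncol(mat)),
                            residues = residues, tier = tiers,
                            stringsAsFactors = FALSE),
       pct_all_conserved = 100 * mean(tiers == "all_conserved"))
}

#' Write alignment outputs
#'
#' \code{writeMsaFasta} writes the gapped sequences; \code{writeTierTsv}
#' the per-column tiers; \code{writeShadedAlignment} a plain-text rendering
#' with a marker line (\code{#} fully conserved, \code{+} conserved in all
#' but one row, space otherwise).
#'
#' @param msa Output of [progressiveMsa()].
#' @param tiers Output of [conservationTiers()].
#' @param path Output path.
#' @param width Characters per block in the text rendering.
#' @export
writeMsaFasta <- function(msa, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(as.character(msa), names(msa))),
    path)
  invisible(path)
}

#' @rdname writeMsaFasta
#' @export
writeTierTsv <- function(tiers, path) {
  utils::write.table(tiers$columns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeMsaFasta
#' @export
writeShadedAlignment <- function(msa, tiers, path, width = 60L) {
  marks <- c(all_conserved = "#", near_conserved = "+", variable = " ")
  markLine <- paste(marks[tiers$columns$tier], collapse = "")
  total <- nchar(msa[[1L]])
  namew <- max(nchar(names(msa)))
  con <- file(path, "w")
  on.exit(close(con))
  for (from in seq(1L, total, by = width)) {
    to <- min(from + width - 1L, total)
    for (s in seq_along(msa)) {
      writeLines(sprintf("%-*s  %s", namew, names(msa)[s],
                         substring(msa[[s]], from, to)), con)
    }
    writeLines(sprintf("%-*s  %s", namew, "",
                       substring(markLine, from, to)), con)
    writeLines("", con)
  }
  invisible(path)
}
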