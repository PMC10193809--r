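# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (per-position run detection, substring enumeration,
# exhaustive alignment search) so they share no code path with the package
# internals they check.

oracleRevComp <- function(nt) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", nt), "")[[1L]]), collapse = "")
}

# Enumerate ORFs by checking, at every genome position, whether a codon run
# starts there (previous in-frame codon is a stop), then extending.
oracleScan <- function(genome, code, minAa, mode = "stop_to_stop",
                       startCodons = "ATG", allDown = FALSE) {
  L <- nchar(genomeSequence(genome))
  circular <- genomeTopology(genome) == "circular"
  tab <- codonTable(code)
  stops <- names(tab)[tab == "*"]
  recs <- list()
  emitRec <- function(strand, p0, len, hasStop, cods) {
    if (len < minAa) return()
    aa <- paste(tab[cods], collapse = "")
    end0 <- (p0 + 3 * len - 1) %% L
    if (strand == "+") {
      refStart <- p0 + 1; refEnd <- end0 + 1
    } else {
      refStart <- L - p0; refEnd <- L - end0
    }
    fr <- if (strand == "+") ((refStart - 1) %% 3) + 1
          else -(((L - refStart) %% 3) + 1)
    recs[[length(recs) + 1L]] <<- data.frame(
      strand = strand, frame = fr, start = refStart, end_no_stop = refEnd,
      has_stop = hasStop,
      wraps_origin = circular && (!hasStop || (p0 + 3 * len) > L),
      aa_sequence = aa, aa_length = len, stringsAsFactors = FALSE)
  }
  handleRun <- function(strand, p0, len, hasStop, codonAt) {
    cps <- (p0 + 3 * (seq_len(len) - 1)) %% L
    cods <- vapply(cps, codonAt, character(1))
    if (mode == "stop_to_stop") {
      emitRec(strand, p0, len, hasStop, cods)
    } else {
      hits <- which(cods %in% startCodons)
      if (!allDown && length(hits)) hits <- hits[1L]
      for (j in hits) {
        emitRec(strand, cps[j], len - j + 1, hasStop, cods[j:len])
      }
    }
  }
  for (strand in c("+", "-")) {
    S <- if (strand == "+") genomeSequence(genome)
         else oracleRevComp(genomeSequence(genome))
    SSS <- paste0(S, S, S)
    codonAt <- function(p0) substr(SSS, p0 + 1, p0 + 3)
    if (circular) {
      ncyc <- if (L %% 3 == 0) L %/% 3 else L
      classes <- if (L %% 3 == 0) 0:2 else 0
      for (cl in classes) {
        cyc <- (cl + 3 * (0:(ncyc - 1))) %% L
        if (!any(vapply(cyc, function(p) codonAt(p) %in% stops,
                        logical(1)))) {
          handleRun(strand, min(cyc), ncyc, FALSE, codonAt)
        }
      }
      for (p in 0:(L - 1)) {
        if (codonAt(p) %in% stops) next
        if (!(codonAt((p - 3) %% L) %in% stops)) next
        len <- 0; q <- p
        while (len < ncyc && !(codonAt(q) %in% stops)) {
          len <- len + 1; q <- (q + 3) %% L
        }
        if (codonAt(q) %in% stops) handleRun(strand, p, len, TRUE, codonAt)
      }
    } else {
      for (f in 0:2) {
        if (L - f < 3) next
        ps <- seq(f, L - 3, by = 3)
        i <- 1
        while (i <= length(ps)) {
          if (codonAt(ps[i]) %in% stops) { i <- i + 1; next }
          j <- i
          while (j <= length(ps) && !(codonAt(ps[j]) %in% stops)) j <- j + 1
          handleRun(strand, ps[i], j - i, j <= length(ps), codonAt)
          i <- j + 1
        }
      }
    }
  }
  if (!length(recs)) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end_no_stop = integer(),
                      has_stop = logical(), wraps_origin = logical(),
                      aa_sequence = character(), aa_length = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out[order(out$strand, out$frame, out$start, out$aa_length), ,
      drop = FALSE]
}

orfKey <- function(d) {
  sprintf("%s|%d|%d|%d|%s|%s|%s", d$strand, d$frame, d$start,
          d$end_no_stop, d$has_stop, d$wraps_origin, d$aa_sequence)
}

expect_scan_matches_oracle <- function(genome, code, minAa, mode,
                                       allDown = FALSE) {
  got <- scanOrfs(genome, code, minAa = minAa, mode = mode,
                  allDownstreamStarts = allDown)
  want <- oracleScan(genome, code, minAa = minAa, mode = mode,
                     allDown = allDown)
  expect_setequal(orfKey(got), orfKey(want))
}

randomGenome <- function(len, topology = "circular") {
  circularGenome(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                              prob = c(0.3, 0.22, 0.18, 0.3)),
                       collapse = ""),
                 id = "rnd", topology = topology)
}

# Tryptic digestion by enumeration of every substring, with vectorised
# boundary/miscleavage/length checks and a mass filter.
oracleDigest <- function(aa, maxMis, minLen, massMin, massMax, prolineRule,
                         massFun = monoisotopicMass) {
  res <- strsplit(aa, "")[[1L]]
  n <- length(res)
  sites <- which(res[-n] %in% c("K", "R"))
  if (prolineRule && length(sites)) sites <- sites[res[sites + 1] != "P"]
  validStart <- c(TRUE, seq_len(n - 1) %in% sites)     # start i valid
  validEnd <- c(seq_len(n - 1) %in% sites, TRUE)       # end j valid
  cs <- c(0, cumsum(seq_len(n) %in% sites))            # cs[m + 1] = sites <= m
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  grid <- grid[grid$j >= grid$i, ]
  mis <- cs[grid$j] - cs[grid$i]                       # sites inside [i, j-1]
  ok <- validStart[grid$i] & validEnd[grid$j] &
    (grid$j - grid$i + 1) >= minLen & mis <= maxMis
  grid <- grid[ok, , drop = FALSE]
  mis <- mis[ok]
  peps <- substring(aa, grid$i, grid$j)
  mass <- vapply(peps, massFun, numeric(1), USE.NAMES = FALSE)
  keep <- mass >= massMin & mass <= massMax
  out <- data.frame(aa_sequence = peps[keep], start_in_parent = grid$i[keep],
                    miscleavages = mis[keep], mass = mass[keep],
                    stringsAsFactors = FALSE)
  out[order(out$start_in_parent, nchar(out$aa_sequence)), , drop = FALSE]
}

randomProtein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Exhaustive alignment search (no memoisation, explicit path enumeration)
# under the same affine convention: gapOpen for the first gapped position,
# gapExtend for each additional.
oracleAlignScore <- function(a, b, match = 1, mismatch = -1,
                             gapOpen = -5, gapExtend = -1) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  rec <- function(i, j, prevOp) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == B[j] && A[i] != "*" && A[i] != "X") match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "d"))
    }
    if (i <= length(A)) {
      cost <- if (prevOp == "u") gapExtend else gapOpen
      best <- max(best, cost + rec(i + 1, j, "u"))
    }
    if (j <= length(B)) {
      cost <- if (prevOp == "l") gapExtend else gapOpen
      best <- max(best, cost + rec(i, j + 1, "l"))
    }
    best
  }
  rec(1, 1, "d")
}
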