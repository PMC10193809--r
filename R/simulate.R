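## Seeded simulator: circular genomes with planted reference genes and
## planted alternative ORFs, plus a machine-readable truth table.
##
## Every plant is embedded as [in-frame stop][ATG][stop-free body][stop],
## so a stop-to-stop (or ATG-initiated) rescan recovers it at exactly its
## planted coordinates. Plants are realised by constraint repair: free
## positions are drawn from the background base composition and locally
## resampled until every frame constraint holds (bounded sweeps, then an
## error naming the plant). Optionally, stop codons are inserted into all
## reading frames outside the planted ORFs until no spurious stop-free run
## of >= suppressAa codons remains, which makes the truth table the
## complete catalogue of ORFs at that length cutoff.

.DEFAULT_BASE_PROBS <- c(A = 0.30, C = 0.25, G = 0.20, T = 0.25)  # A+T 55%

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Describe one ORF to plant in a synthetic genome
#'
#' @param kind One of \code{reference_gene}, \code{sense_frameshift},
#'   \code{antisense}, \code{rna_resident}, \code{intergenic}.
#' @param aaLength Peptide length in residues (including the initiator
#'   methionine); at least 1.
#' @param name Plant name (autogenerated if missing).
#' @param host Host plant/feature name; required for
#'   \code{sense_frameshift} and \code{antisense}, optional for
#'   \code{rna_resident} (a new RNA feature is created when absent).
#' @param frameOffset Requested nucleotide offset (1 or 2) relative to the
#'   host reading frame; required for \code{sense_frameshift}.
#' @param strand Strand of the plant (for \code{reference_gene} and
#'   \code{rna_resident}; sub-plants derive theirs from the host).
#' @param startHint 1-based reference position of the first coding base, or
#'   NA for seeded-random placement.
#' @param rnaType For \code{rna_resident} without a host: \code{"rRNA"} or
#'   \code{"tRNA"}.
#' @return A \code{PlantSpec} list.
#' @export
plantSpec <- function(kind = c("reference_gene", "sense_frameshift",
                               "antisense", "rna_resident", "intergenic"),
                      aaLength, name = NULL, host = NA_character_,
                      frameOffset = NA_integer_, strand = "+",
                      startHint = NA_integer_, rnaType = "rRNA") {
  kind <- match.arg(kind)
  if (aaLength < 1L) stop("aaLength must be >= 1", call. = FALSE)
  if (kind == "sense_frameshift" &&
      (is.na(host) || !frameOffset %in% c(1L, 2L))) {
    stop("sense_frameshift needs a host and a frameOffset of 1 or 2",
         call. = FALSE)
  }
  if (kind == "antisense" && is.na(host)) {
    stop("antisense needs a host", call. = FALSE)
  }
  structure(list(kind = kind, aaLength = as.integer(aaLength),
                 name = name, host = host,
                 frameOffset = as.integer(frameOffset), strand = strand,
                 startHint = as.integer(startHint), rnaType = rnaType),
            class = "PlantSpec")
}

## ---- synthesis engine ----------------------------------------------------

.arcPos <- function(pos0, L) (pos0 + 0:2) %% L + 1L

.newState <- function(L, baseProbs) {
  env <- new.env(parent = emptyenv())
  env$L <- L
  env$nt <- sample(names(baseProbs), L, replace = TRUE, prob = baseProbs)
  env$locked <- rep(FALSE, L)
  env$baseProbs <- baseProbs
  env
}

.setHard <- function(env, pos0, pattern, plant) {
  idx <- .arcPos(pos0, env$L)
  ch <- strsplit(pattern, "")[[1L]]
  clash <- env$locked[idx] & env$nt[idx] != ch
  if (any(clash)) {
    stop(sprintf("infeasible plant '%s': clashes with a locked position",
                 plant), call. = FALSE)
  }
  env$nt[idx] <- ch
  env$locked[idx] <- TRUE
  invisible(env)
}

.tripletAt <- function(env, pos0) {
  idx <- .arcPos(pos0, env$L)
  paste(env$nt[idx], collapse = "")
}

## forbid: data.frame(pos0, strand, plant); codon arcs that must not be
## stops (the planted ORF bodies, read on their own strand).
.forbidViolations <- function(env, forbid, stopsPlus, stopsMinusPat) {
  seqStr <- paste(env$nt, collapse = "")
  SS <- paste0(seqStr, substr(seqStr, 1L, 2L))
  tri <- substring(SS, forbid$pos0 + 1L, forbid$pos0 + 3L)
  which((forbid$strand == "+" & tri %in% stopsPlus) |
        (forbid$strand == "-" & tri %in% stopsMinusPat))
}

.repairForbidden <- function(env, forbid, stopsPlus, stopsMinusPat,
                             maxSweeps = 500L) {
  if (!nrow(forbid)) return(invisible(env))
  for (sweep in seq_len(maxSweeps)) {
    bad <- .forbidViolations(env, forbid, stopsPlus, stopsMinusPat)
    if (!length(bad)) return(invisible(env))
    for (i in bad) {
      idx <- .arcPos(forbid$pos0[i], env$L)
      free <- idx[!env$locked[idx]]
      if (!length(free)) {
        stop(sprintf("infeasible plant '%s': locked codon forced to a stop",
                     forbid$plant[i]), call. = FALSE)
      }
      env$nt[free] <- sample(names(env$baseProbs), length(free),
                             replace = TRUE, prob = env$baseProbs)
    }
  }
  bad <- .forbidViolations(env, forbid, stopsPlus, stopsMinusPat)
  stop(sprintf("infeasible plant '%s': stop-free constraint not satisfied after %d sweeps",
               forbid$plant[bad[1L]], maxSweeps), call. = FALSE)
}

## Stop indicator for every codon of a frame. Frames are keyed by strand
## and the residue class r of the 0-based arc start (L must be divisible
## by 3 so codon cycles are disjoint).
.frameStops <- function(env, r, strand, stopsPlus, stopsMinusPat) {
  L <- env$L
  starts0 <- r + 3L * (seq_len(L %/% 3L) - 1L)
  seqStr <- paste(env$nt, collapse = "")
  SS <- paste0(seqStr, substr(seqStr, 1L, 2L))
  tri <- substring(SS, starts0 + 1L, starts0 + 3L)
  stops <- if (strand == "+") stopsPlus else stopsMinusPat
  list(starts0 = starts0, isStop = tri %in% stops)
}

## Cyclic stop-free gaps (runs of codons between stops) of one frame.
.cyclicGaps <- function(isStop) {
  n <- length(isStop)
  iStops <- which(isStop)
  if (!length(iStops)) {
    return(list(list(idx = seq_len(n))))
  }
  gaps <- list()
  nS <- length(iStops)
  for (si in seq_len(nS)) {
    from <- iStops[si] + 1L
    to <- (if (si < nS) iStops[si + 1L] else iStops[1L] + n) - 1L
    if (to < from) next
    gaps[[length(gaps) + 1L]] <- list(idx = ((from:to - 1L) %% n) + 1L)
  }
  gaps
}

## Try to turn codon arc pos0 into a stop on the given strand without
## violating any forbidden codon; returns TRUE on success.
.tryInsertStop <- function(env, pos0, strand, stopsPlus, stopsMinusPat,
                           forbid, forbidByPos) {
  patterns <- if (strand == "+") stopsPlus else stopsMinusPat
  idx <- .arcPos(pos0, env$L)
  for (pat in patterns) {
    ch <- strsplit(pat, "")[[1L]]
    if (any(env$locked[idx] & env$nt[idx] != ch)) next
    oldNt <- env$nt[idx]
    env$nt[idx] <- ch
    ## check forbidden codons overlapping the modified positions
    ok <- TRUE
    touched <- unique(unlist(forbidByPos[idx]))
    for (fi in touched) {
      tri <- .tripletAt(env, forbid$pos0[fi])
      stops <- if (forbid$strand[fi] == "+") stopsPlus else stopsMinusPat
      if (tri %in% stops) { ok <- FALSE; break }
    }
    if (ok) {
      env$locked[idx] <- TRUE
      return(TRUE)
    }
    env$nt[idx] <- oldNt
  }
  FALSE
}

## Insert stops until no frame has a non-exempt stop-free run of
## >= suppressAa codons. exempt: named list frameKey -> set of arc starts
## that must not receive a stop (the planted ORFs' own codons).
.suppressRuns <- function(env, suppressAa, exempt, forbid,
                          stopsPlus, stopsMinusPat, maxPasses = 40L) {
  L <- env$L
  forbidByPos <- vector("list", L)
  for (fi in seq_len(nrow(forbid))) {
    for (p in .arcPos(forbid$pos0[fi], L)) {
      forbidByPos[[p]] <- c(forbidByPos[[p]], fi)
    }
  }
  frames <- expand.grid(r = 0:2, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  for (pass in seq_len(maxPasses)) {
    dirty <- FALSE
    for (f in seq_len(nrow(frames))) {
      r <- frames$r[f]; strand <- frames$strand[f]
      key <- paste0(strand, r)
      ex <- exempt[[key]]
      fs <- .frameStops(env, r, strand, stopsPlus, stopsMinusPat)
      gaps <- .cyclicGaps(fs$isStop)
      for (gap in gaps) {
        if (length(gap$idx) < suppressAa) next
        starts <- fs$starts0[gap$idx]
        free <- if (is.null(ex)) starts else setdiff(starts, ex)
        if (!length(free)) next  # a planted ORF's own run
        dirty <- TRUE
        ## try positions from the middle of the gap outwards so inserted
        ## stops split gaps roughly in half
        ord <- order(abs(seq_along(free) - (length(free) + 1L) / 2))
        placed <- FALSE
        for (p0 in free[ord]) {
          if (.tryInsertStop(env, p0, strand, stopsPlus, stopsMinusPat,
                             forbid, forbidByPos)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not suppress a spurious open reading frame; ",
               "genome too constrained", call. = FALSE)
        }
      }
    }
    if (!dirty) return(invisible(env))
  }
  ## final verification happens in the caller
  invisible(env)
}

## ---- placement -----------------------------------------------------------

## A placement fully determines a plant's geometry: 0-based footprint
## start q, covering [pre-stop][ATG][body][stop] = 3*aa + 6 nt.
.plantGeometry <- function(q, aa, strand, L) {
  if (strand == "+") {
    list(orfStart = (q + 3L) %% L + 1L,
         orfEnd = (q + 3L * aa + 2L) %% L + 1L,
         annStart = (q + 3L) %% L + 1L,
         annEnd = (q + 3L * aa + 5L) %% L + 1L)
  } else {
    list(orfStart = (q + 3L * aa + 2L) %% L + 1L,
         orfEnd = (q + 3L) %% L + 1L,
         annStart = q %% L + 1L,
         annEnd = (q + 3L * aa + 2L) %% L + 1L)
  }
}

.applyPlant <- function(env, pl) {
  q <- pl$q; aa <- pl$aa
  if (pl$strand == "+") {
    .setHard(env, q, "TAA", pl$name)
    .setHard(env, q + 3L, "ATG", pl$name)
    .setHard(env, q + 3L * aa + 3L, "TAA", pl$name)
  } else {
    .setHard(env, q, "TTA", pl$name)                 # minus-strand stop
    .setHard(env, q + 3L * aa, "CAT", pl$name)       # minus-strand ATG
    .setHard(env, q + 3L * aa + 3L, "TTA", pl$name)  # minus pre-stop
  }
  invisible(env)
}

.plantForbid <- function(pl, L) {
  aa <- pl$aa
  if (aa < 2L) {
    return(data.frame(pos0 = integer(), strand = character(),
                      plant = character(), stringsAsFactors = FALSE))
  }
  pos0 <- if (pl$strand == "+") pl$q + 6L + 3L * (seq_len(aa - 1L) - 1L)
          else pl$q + 3L + 3L * (seq_len(aa - 1L) - 1L)
  data.frame(pos0 = pos0 %% L, strand = pl$strand, plant = pl$name,
             stringsAsFactors = FALSE)
}

.plantExemptArcs <- function(pl, L) {
  (pl$q + 3L * seq_len(pl$aa)) %% L  # ATG arc through last body arc
}

.plantFrameKey <- function(pl) paste0(pl$strand, pl$q %% 3L)

## Place sub-plants (sense_frameshift / antisense) inside their host.
.placeInsideHost <- function(spec, hostPl, L) {
  aaA <- spec$aaLength; qh <- hostPl$q; aaH <- hostPl$aa
  lo <- qh + 3L          # first free arc inside host
  hi <- qh + 3L * aaH - 1L - (3L * aaA + 5L)
  if (hostPl$strand == "+") lo <- qh + 6L  # keep clear of host ATG
  if (hi < lo) {
    stop(sprintf("infeasible plant '%s': host '%s' too short",
                 spec$name, hostPl$name), call. = FALSE)
  }
  cand <- lo:hi
  if (spec$kind == "sense_frameshift") {
    want <- if (hostPl$strand == "+") (qh + spec$frameOffset) %% 3L
            else (qh - spec$frameOffset) %% 3L
    cand <- cand[cand %% 3L == want]
    strand <- hostPl$strand
  } else {
    strand <- if (hostPl$strand == "+") "-" else "+"
    if (spec$kind == "antisense") {
      ## avoid accidental same-frame tie: any arc class is fine
    }
  }
  if (!length(cand)) {
    stop(sprintf("infeasible plant '%s': no feasible position in host '%s'",
                 spec$name, hostPl$name), call. = FALSE)
  }
  q <- if (!is.na(spec$startHint)) {
    qq <- if (strand == "+") spec$startHint - 4L
          else spec$startHint - 3L * aaA - 3L
    if (!qq %in% cand) {
      stop(sprintf("infeasible plant '%s': startHint outside host",
                   spec$name), call. = FALSE)
    }
    qq
  } else if (length(cand) == 1L) cand else sample(cand, 1L)
  list(q = q %% L, strand = strand)
}

## ---- generator -----------------------------------------------------------

#' Generate a synthetic circular genome with planted ORFs
#'
#' Draws a background sequence at the requested per-codon stop probability
#' in frame 1 (codons aligned to position 1), then embeds each plant so
#' that its own frame is stop-free for \code{aaLength} codons between
#' flanking stop codons, a sense-frameshift plant sits inside its host at
#' the requested nucleotide offset without putting stops into the host
#' frame, and an antisense plant's reverse-strand frame is stop-free while
#' the host strand stays intact. When plants are present, stop codons are
#' additionally inserted into all frames outside the planted ORFs until no
#' spurious stop-free run of \code{suppressAa} codons remains (set
#' \code{suppressAa = NA} for raw density-controlled background), so the
#' truth table is the complete ORF catalogue at that cutoff. Identical
#' seeds give identical output.
#'
#' @param length Genome length in nt; must be a multiple of 3 so the three
#'   codon cycles per strand stay disjoint (the human mtDNA length is).
#' @param code A [GeneticCode-class].
#' @param plants List of [plantSpec()] objects.
#' @param backgroundStopDensity Per-codon stop probability of the frame-1
#'   background draw (0.05 is close to the uniform-random rate).
#' @param seed Mandatory integer seed.
#' @param baseProbs Background base composition (default mtDNA-like,
#'   A+T = 55\%).
#' @param suppressAa Minimum spurious ORF length to suppress, in codons;
#'   defaults to 20 when plants are present, otherwise off.
#' @return A list with \code{genome} ([CircularGenome-class]),
#'   \code{annotations} (data.frame) and \code{truth} (data.frame: plant
#'   name, kind, strand, frame, start, end_no_stop, aa_length,
#'   aa_sequence, expected category, host, frame_offset).
#' @export
generateGenome <- function(length, code, plants = list(),
                           backgroundStopDensity = 0.05, seed,
                           baseProbs = .DEFAULT_BASE_PROBS,
                           suppressAa = if (length(plants)) 20L else NA) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  L <- as.integer(length)
  if (L %% 3L != 0L) stop("length must be a multiple of 3", call. = FALSE)
  .withSeed(seed, {
    .generateImpl(L, code, plants, backgroundStopDensity, baseProbs,
                  suppressAa, genomeIdStr = sprintf("synth_%d", seed))
  })
}

.generateImpl <- function(L, code, plants, backgroundStopDensity, baseProbs,
                          suppressAa, genomeIdStr,
                          fixedFeatures = NULL, fixedPlacements = NULL) {
  stopsPlus <- code@stopCodons
  stopsMinusPat <- vapply(stopsPlus, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1L), USE.NAMES = FALSE)
  ## name the plants
  specs <- plants
  for (i in seq_along(specs)) {
    if (is.null(specs[[i]]$name)) specs[[i]]$name <- sprintf("plant%02d", i)
  }
  topKinds <- c("reference_gene", "rna_resident", "intergenic")
  footprint <- function(aa) 3L * aa + 6L
  total <- sum(vapply(specs, function(s) footprint(s$aaLength), integer(1L)))
  if (total > L) stop("total planted footprint exceeds genome length",
                      call. = FALSE)
  ## --- placement ---
  placements <- list()
  if (!is.null(fixedPlacements)) {
    placements <- fixedPlacements
  } else {
    cursor <- 0L
    for (s in specs[vapply(specs, function(x) x$kind %in% topKinds,
                           logical(1L))]) {
      fp <- footprint(s$aaLength)
      q <- if (!is.na(s$startHint)) {
        if (s$strand == "+") s$startHint - 4L
        else s$startHint - 3L * s$aaLength - 3L
      } else {
        cursor + sample(6:30, 1L)
      }
      if (q + fp > L - 3L) {
        stop(sprintf("infeasible plant '%s': does not fit", s$name),
             call. = FALSE)
      }
      placements[[s$name]] <- list(name = s$name, kind = s$kind,
                                   strand = s$strand, q = q %% L,
                                   aa = s$aaLength, host = s$host,
                                   offset = s$frameOffset,
                                   rnaType = s$rnaType)
      cursor <- max(cursor, q + fp)
    }
    for (s in specs[vapply(specs, function(x)
      x$kind %in% c("sense_frameshift", "antisense"), logical(1L))]) {
      hostPl <- placements[[s$host]]
      if (is.null(hostPl) || hostPl$kind != "reference_gene") {
        stop(sprintf("plant '%s': host '%s' is not a planted reference gene",
                     s$name, s$host), call. = FALSE)
      }
      pos <- .placeInsideHost(s, hostPl, L)
      placements[[s$name]] <- list(name = s$name, kind = s$kind,
                                   strand = pos$strand, q = pos$q,
                                   aa = s$aaLength, host = s$host,
                                   offset = s$frameOffset,
                                   rnaType = NA_character_)
    }
  }
  ## --- synthesis ---
  env <- .newState(L, baseProbs)
  inPlant <- rep(FALSE, L)
  for (pl in placements) {
    idx <- (pl$q + 0:(footprint(pl$aa) - 1L)) %% L + 1L
    inPlant[idx] <- TRUE
  }
  if (!is.na(backgroundStopDensity)) {
    nonStop <- names(code@codonToAa)[code@codonToAa != "*"]
    w <- vapply(strsplit(nonStop, ""), function(ch)
      prod(baseProbs[ch]), numeric(1L))
    grid <- seq.int(0L, L - 3L, by = 3L)
    bg <- grid[vapply(grid, function(p) all(!inPlant[.arcPos(p, L)]),
                      logical(1L))]
    isStop <- stats::runif(length(bg)) < backgroundStopDensity
    for (k in seq_along(bg)) {
      idx <- .arcPos(bg[k], L)
      tri <- if (isStop[k]) sample(stopsPlus, 1L)
             else sample(nonStop, 1L, prob = w)
      env$nt[idx] <- strsplit(tri, "")[[1L]]
    }
  }
  ## plants may overlap only through a host relationship
  pn <- names(placements)
  for (i in seq_along(placements)) {
    for (j in seq_len(i - 1L)) {
      a <- placements[[i]]; b <- placements[[j]]
      if (identical(a$host, b$name) || identical(b$host, a$name)) next
      ov <- .circOverlap(a$q, footprint(a$aa), b$q, footprint(b$aa), L)
      if (ov > 0L) {
        stop(sprintf("plants '%s' and '%s' overlap without a host relation",
                     pn[i], pn[j]), call. = FALSE)
      }
    }
  }
  forbid <- do.call(rbind, c(list(data.frame(pos0 = integer(),
                                             strand = character(),
                                             plant = character(),
                                             stringsAsFactors = FALSE)),
                             lapply(placements, .plantForbid, L = L)))
  for (pl in placements) .applyPlant(env, pl)
  .repairForbidden(env, forbid, stopsPlus, stopsMinusPat)
  if (!is.na(suppressAa)) {
    exempt <- list()
    for (pl in placements) {
      key <- .plantFrameKey(pl)
      exempt[[key]] <- c(exempt[[key]], .plantExemptArcs(pl, L))
    }
    .suppressRuns(env, suppressAa, exempt, forbid, stopsPlus, stopsMinusPat)
  }
  genome <- circularGenome(paste(env$nt, collapse = ""), id = genomeIdStr)
  ## --- annotations ---
  ann <- if (!is.null(fixedFeatures)) fixedFeatures else {
    rows <- list()
    for (pl in placements) {
      geo <- .plantGeometry(pl$q, pl$aa, pl$strand, L)
      if (pl$kind == "reference_gene") {
        rows[[length(rows) + 1L]] <- data.frame(
          name = pl$name, feature_type = "protein_coding",
          start = min(geo$annStart, geo$annEnd),
          end = max(geo$annStart, geo$annEnd),
          strand = pl$strand, wraps = FALSE, stringsAsFactors = FALSE)
      } else if (pl$kind == "rna_resident" && is.na(pl$host)) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = paste0(pl$name, "_", pl$rnaType),
          feature_type = pl$rnaType,
          start = min(geo$annStart, geo$annEnd),
          end = max(geo$annStart, geo$annEnd),
          strand = "+", wraps = FALSE, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      geneAnnotations(character(), character(), integer(), integer())
  }
  ## --- truth table ---
  truth <- .truthTable(placements, ann, genome, code, L)
  list(genome = genome, annotations = ann, truth = truth)
}

.truthTable <- function(placements, ann, genome, code, L) {
  rows <- list()
  S <- genomeSequence(genome)
  SS <- paste0(S, S)
  for (pl in placements) {
    geo <- .plantGeometry(pl$q, pl$aa, pl$strand, L)
    cds0 <- (pl$q + 3L) %% L  # 0-based low end of the coding arc
    ntStr <- substring(SS, cds0 + 1L, cds0 + 3L * pl$aa)
    if (pl$strand == "-") ntStr <- revComp(ntStr)
    aaSeq <- translateCds(ntStr, code)$aa
    category <- switch(pl$kind,
      reference_gene = "matches_reference",
      sense_frameshift = "sense_frameshift",
      antisense = "antisense",
      rna_resident = {
        hostName <- if (!is.na(pl$host)) pl$host else
          paste0(pl$name, "_", pl$rnaType)
        tp <- ann$feature_type[ann$name == hostName][1L]
        if (identical(tp, "tRNA")) "within_tRNA" else "within_rRNA"
      },
      intergenic = "intergenic")
    hostName <- if (pl$kind == "reference_gene") pl$name
      else if (pl$kind == "rna_resident") {
        if (!is.na(pl$host)) pl$host else paste0(pl$name, "_", pl$rnaType)
      } else pl$host
    rows[[length(rows) + 1L]] <- data.frame(
      name = pl$name, kind = pl$kind, strand = pl$strand,
      frame = frameOf(geo$orfStart, pl$strand, L),
      start = geo$orfStart, end_no_stop = geo$orfEnd,
      aa_length = pl$aa, aa_sequence = aaSeq,
      category = category,
      host = if (pl$kind == "intergenic") NA_character_ else hostName,
      frame_offset = if (pl$kind == "reference_gene") 0L
                     else if (pl$kind == "sense_frameshift") pl$offset
                     else NA_integer_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## ---- mitochondria-like layout -------------------------------------------

.MITO_GENES <- c(nd1 = 318L, nd2 = 347L, cox1 = 513L, cox2 = 227L,
                 atp8 = 68L, atp6 = 226L, cox3 = 261L, nd3 = 115L,
                 nd4l = 98L, nd4 = 459L, nd5 = 603L, nd6 = 174L,
                 cytb = 380L)

.MITO_TRNAS <- c("trnF", "trnV", "trnL1", "trnI", "trnQ", "trnM", "trnW",
                 "trnA", "trnN", "trnC", "trnY", "trnS1", "trnD", "trnK",
                 "trnG", "trnR", "trnH", "trnS2", "trnL2", "trnE", "trnT",
                 "trnP")

#' Generate a mitochondria-like synthetic genome with planted altORFs
#'
#' Builds a ~16.9 kb circular genome laid out like an animal mitogenome:
#' 13 protein-coding genes (one on the minus strand, as for human ND6),
#' 2 rRNAs, 22 tRNAs and one D-loop in a tight head-to-tail arrangement
#' with 4-nt spacers (38 annotations in total), plus six planted
#' alternative ORFs covering every plant kind: two sense frameshifts
#' (offsets 1 and 2) inside genes, one antisense ORF inside a gene, one
#' rRNA-resident and one tRNA-resident ORF, and one intergenic ORF in a
#' 200-nt unannotated gap. Stop codons are inserted in all frames outside
#' the plants so that the truth table is the complete catalogue of ORFs of
#' at least \code{suppressAa} codons: a scan plus
#' [filterUnannotated()] recovers exactly the six planted altORFs.
#'
#' @param seed Mandatory integer seed.
#' @param code Genetic code used for planting and translation.
#' @param suppressAa Spurious-ORF suppression threshold in codons; matches
#'   the downstream scan's \code{minAa} (default 20).
#' @return A list with \code{genome}, \code{annotations} and \code{truth}
#'   as for [generateGenome()].
#' @export
emulateMitoLayout <- function(seed,
                              code = loadGeneticCode("vertebrate_mito_modified"),
                              suppressAa = 20L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  .withSeed(seed, {
    spacer <- 4L
    dLoopLen <- 1101L
    rrnLens <- c(rrnS = 954L, rrnL = 1559L)
    trnLens <- stats::setNames(rep(69L, length(.MITO_TRNAS)), .MITO_TRNAS)
    trnLens["trnL1"] <- 75L  # hosts the tRNA-resident plant
    order <- c("D_loop", "trnF", "rrnS", "trnV", "rrnL", "trnL1", "nd1",
               "trnI", "trnQ", "trnM", "nd2", "trnW", "trnA", "trnN",
               "trnC", "trnY", "cox1", "trnS1", "trnD", "cox2", "trnK",
               "atp8", "atp6", "cox3", "trnG", "nd3", "trnR", "nd4l",
               "nd4", "trnH", "trnS2", "trnL2", "nd5", "nd6", "trnE",
               "cytb", "trnT", "trnP")
    featLen <- function(nm) {
      if (nm == "D_loop") dLoopLen
      else if (nm %in% names(rrnLens)) rrnLens[[nm]]
      else if (nm %in% names(trnLens)) trnLens[[nm]]
      else 3L * .MITO_GENES[[nm]] + 3L
    }
    gap <- 200L
    L <- sum(vapply(order, featLen, integer(1L))) +
      spacer * length(order) + gap
    dLoopLen <- dLoopLen + (3L - L %% 3L) %% 3L
    L <- L + (3L - L %% 3L) %% 3L
    cursor <- 1L
    featRows <- list()
    placements <- list()
    for (nm in order) {
      len <- featLen(nm)
      if (nm == "D_loop") len <- dLoopLen
      fs <- cursor; fe <- cursor + len - 1L
      type <- if (nm == "D_loop") "D_loop"
        else if (nm %in% names(rrnLens)) "rRNA"
        else if (nm %in% names(trnLens)) "tRNA"
        else "protein_coding"
      strand <- if (nm == "nd6") "-" else "+"
      featRows[[nm]] <- data.frame(name = nm, feature_type = type,
                                   start = fs, end = fe, strand = strand,
                                   wraps = FALSE, stringsAsFactors = FALSE)
      if (type == "protein_coding") {
        aa <- .MITO_GENES[[nm]]
        q <- if (strand == "+") fs - 4L else fs - 1L  # 0-based footprint
        placements[[nm]] <- list(name = nm, kind = "reference_gene",
                                 strand = strand, q = q %% L, aa = aa,
                                 host = NA_character_,
                                 offset = NA_integer_,
                                 rnaType = NA_character_)
      }
      cursor <- fe + 1L + spacer
    }
    gapStart <- cursor; gapEnd <- L  # unannotated gap closes the circle
    ann <- do.call(rbind, featRows)
    rownames(ann) <- NULL
    ## hosted altORF plants
    altSpecs <- list(
      plantSpec("sense_frameshift", aaLength = 33L, name = "alt_nd4_fs2",
                host = "nd4", frameOffset = 2L),
      plantSpec("sense_frameshift", aaLength = 28L, name = "alt_nd2_fs1",
                host = "nd2", frameOffset = 1L),
      plantSpec("antisense", aaLength = 40L, name = "alt_cox3_as",
                host = "cox3"))
    for (s in altSpecs) {
      pos <- .placeInsideHost(s, placements[[s$host]], L)
      placements[[s$name]] <- list(name = s$name, kind = s$kind,
                                   strand = pos$strand, q = pos$q,
                                   aa = s$aaLength, host = s$host,
                                   offset = s$frameOffset,
                                   rnaType = NA_character_)
    }
    placeInFeature <- function(name, kind, aa, featName, lo1, hi1) {
      fp <- 3L * aa + 6L
      cand <- (lo1 - 1L):(hi1 - fp)  # 0-based footprint starts
      if (!length(cand) || cand[1L] > cand[length(cand)]) {
        stop(sprintf("infeasible plant '%s': feature too short", name),
             call. = FALSE)
      }
      q <- if (length(cand) == 1L) cand else sample(cand, 1L)
      list(name = name, kind = kind, strand = "+", q = q %% L,
           aa = aa, host = featName, offset = NA_integer_,
           rnaType = NA_character_)
    }
    rrnL <- ann[ann$name == "rrnL", ]
    trnL1 <- ann[ann$name == "trnL1", ]
    placements[["alt_rrnL"]] <- placeInFeature("alt_rrnL", "rna_resident",
                                               24L, "rrnL",
                                               rrnL$start, rrnL$end)
    placements[["alt_trnL1"]] <- placeInFeature("alt_trnL1", "rna_resident",
                                                20L, "trnL1",
                                                trnL1$start, trnL1$end)
    placements[["alt_inter"]] <- placeInFeature("alt_inter", "intergenic",
                                                22L, NA_character_,
                                                gapStart, gapEnd)
    placements[["alt_inter"]]$host <- NA_character_
    .generateImpl(L, code, plants = list(),
                  backgroundStopDensity = NA, baseProbs = .DEFAULT_BASE_PROBS,
                  suppressAa = suppressAa,
                  genomeIdStr = sprintf("mitoSim_%d", seed),
                  fixedFeatures = ann, fixedPlacements = placements)
  })
}
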