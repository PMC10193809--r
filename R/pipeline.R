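## End-to-end discovery pipeline and the candidate report.

#' Assemble a discovery run configuration
#'
#' @param genome A [CircularGenome-class] or a FASTA path.
#' @param annotations An annotation data.frame, a GFF3 path, or NULL.
#' @param codeName Genetic-code name for [loadGeneticCode()].
#' @param mode Scan mode, \code{"stop_to_stop"} (discovery default) or
#'   \code{"atg_initiated"}.
#' @param minAa Minimum peptide length (default 20 aa = 60 coding nt,
#'   counted without the stop codon).
#' @param digest A [digestParams()] object.
#' @param knownOrfs Known-micropeptide table ([readKnownOrfs()]), a path,
#'   or NULL.
#' @param startCodons Start-codon set for ATG mode.
#' @param allDownstreamStarts Surface every in-frame start codon.
#' @param outDir Output directory, or NULL for in-memory results only.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(genome, annotations = NULL,
                      codeName = "vertebrate_mito_modified",
                      mode = "stop_to_stop", minAa = 20L,
                      digest = digestParams(), knownOrfs = NULL,
                      startCodons = "ATG", allDownstreamStarts = FALSE,
                      outDir = NULL) {
  if (is.character(genome)) genome <- readCircularGenome(genome)
  if (is.character(annotations)) annotations <- readAnnotationsGff3(annotations)
  if (is.character(knownOrfs)) knownOrfs <- readKnownOrfs(knownOrfs)
  structure(list(genome = genome, annotations = annotations,
                 codeName = codeName, mode = mode, minAa = as.integer(minAa),
                 digest = digest, knownOrfs = knownOrfs,
                 startCodons = startCodons,
                 allDownstreamStarts = allDownstreamStarts,
                 outDir = outDir),
            class = "RunConfig")
}

## Report dialect for the position column: "Within <gene> sense,
## frameshift <a> to <b>" / "<gene> anti-sense <a> to <b>" / plain ranges.
.positionString <- function(row) {
  a <- row$start; b <- row$end_no_stop
  switch(row$category,
    matches_reference = sprintf("%s reference %d to %d",
                                row$host_feature, a, b),
    sense_frameshift = sprintf("Within %s sense, frameshift %d to %d",
                               row$host_feature, a, b),
    antisense = sprintf("%s anti-sense %d to %d", row$host_feature, a, b),
    within_rRNA = sprintf("Within %s %d to %d", row$host_feature, a, b),
    within_tRNA = sprintf("Within %s %d to %d", row$host_feature, a, b),
    multi_feature = sprintf("Across %s %d to %d", row$host_feature, a, b),
    sprintf("intergenic %d to %d", a, b))
}

#' Run the full altORF discovery pipeline
#'
#' Executes scan, classification, removal of reference/known ORFs, peptide
#' property computation and in-silico digestion, and assembles the
#' candidate report. When \code{outDir} is set, writes
#' \code{candidates.tsv}, \code{peptides.fasta}, \code{orfs.bed},
#' \code{orfs.gff3}, \code{digest.tsv}, \code{peptide_list.txt} and
#' \code{run.log}; partial outputs are removed if a stage fails. The log
#' records every defaulted parameter (start-codon policy, proline rule,
#' mass kind, length-cutoff interpretation) so reproduction runs are
#' self-documenting. Re-running an identical configuration yields
#' byte-identical outputs.
#'
#' @param config A [runConfig()] object.
#' @return A list with \code{candidates} (the report data.frame),
#'   \code{orfs} (all scanned records), \code{queries} (digestion table)
#'   and \code{log} (character vector).
#' @export
runDiscovery <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  code <- loadGeneticCode(config$codeName)
  L <- length(config$genome)
  log <- c(
    sprintf("genome: %s (%d nt, %s)", genomeId(config$genome), L,
            genomeTopology(config$genome)),
    sprintf("genetic code: %s (stops: %s)", codeName(code),
            paste(sort(stopCodons(code)), collapse = ",")),
    sprintf("scan mode: %s; min peptide length: %d aa (stop codon not counted)",
            config$mode, config$minAa),
    sprintf("start codons (ATG mode): %s; all downstream starts: %s",
            paste(config$startCodons, collapse = ","),
            config$allDownstreamStarts),
    sprintf("digestion: <=%d miscleavages, >=%d aa, %g-%g Da, proline rule %s, %s mass",
            config$digest$maxMiscleavages, config$digest$minLen,
            config$digest$massMin, config$digest$massMax,
            ifelse(config$digest$prolineRule, "on", "off"),
            config$digest$massKind))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  orfs <- stage("scan", scanOrfs(config$genome, code, minAa = config$minAa,
                                 mode = config$mode,
                                 startCodons = config$startCodons,
                                 allDownstreamStarts = config$allDownstreamStarts))
  log <- c(log, sprintf("scan: %d ORF records", nrow(orfs)))
  ann <- config$annotations
  if (is.null(ann) || !nrow(ann)) {
    ann <- geneAnnotations(character(), character(), integer(), integer())
  }
  candidates <- stage("classify",
                      filterUnannotated(orfs, ann, L,
                                        knownOrfs = config$knownOrfs))
  log <- c(log, sprintf("unannotated candidates: %d (removed %d reference/known)",
                        nrow(candidates), nrow(orfs) - nrow(candidates)))
  prof <- stage("properties", peptideProfile(candidates$aa_sequence))
  candidates$predicted_mw_kda <- prof$mass_kda_1dp
  candidates$average_mass <- prof$average_mass
  candidates$position <- vapply(seq_len(nrow(candidates)), function(i)
    .positionString(candidates[i, ]), character(1L))
  queries <- stage("digest", {
    peps <- stats::setNames(candidates$aa_sequence, candidates$orf_id)
    digestPeptides(peps, config$digest)
  })
  log <- c(log, sprintf("digestion: %d peptide queries", nrow(queries)))
  report <- candidates[, c("orf_id", "aa_sequence", "aa_length",
                           "predicted_mw_kda", "position", "category",
                           "frame_offset", "start", "end_no_stop",
                           "strand", "frame", "host_feature")]
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    written <- character()
    tryCatch({
      p <- file.path(config$outDir, "candidates.tsv")
      utils::write.table(report, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, p)
      p <- file.path(config$outDir, "peptides.fasta")
      writeOrfFasta(candidates, p); written <- c(written, p)
      p <- file.path(config$outDir, "orfs.bed")
      writeOrfBed(candidates, p, L); written <- c(written, p)
      p <- file.path(config$outDir, "orfs.gff3")
      writeOrfGff3(candidates, p, L); written <- c(written, p)
      p <- file.path(config$outDir, "digest.tsv")
      writeDigestTsv(queries, p); written <- c(written, p)
      p <- file.path(config$outDir, "peptide_list.txt")
      writePeptideList(queries, p); written <- c(written, p)
      writeLines(log, file.path(config$outDir, "run.log"))
    }, error = function(e) {
      unlink(written)
      stop(sprintf("[write] %s", conditionMessage(e)), call. = FALSE)
    })
  }
  list(candidates = report, orfs = orfs, queries = queries, log = log)
}
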