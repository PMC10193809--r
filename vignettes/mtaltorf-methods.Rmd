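---
title: "Finding alternative ORFs in circular mitochondrial genomes: models and choices"
author: "mtaltorf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding alternative ORFs in circular mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtaltorf)
```

## The problem

Animal mitochondrial genomes are small circular molecules in which genes
sit head-to-tail with almost no intergenic space. The classic annotation
of the human mitogenome lists 37 genes (13 protein-coding, 2 rRNAs, 22
tRNAs) plus a control region (D-loop). Yet genes can hide inside genes:
an *alternative ORF* (altORF) is a reading frame nested in, antisense to,
or overlapping an annotated gene, read in a different frame than the
reference coding sequence. Several mitochondrial micropeptides of this
kind (Humanin, the SHLPs, MOTS-c, SHMOOSE, and a 99-residue peptide
encoded inside *nd4*) have been characterised, and every silent mutation
in a reference gene is potentially non-silent in an overlapping altORF.

`mtaltorf` implements the discovery side of this problem as a reusable,
fully testable pipeline: six-frame ORF enumeration on a circular genome
under a configurable genetic code, classification of each ORF against the
reference annotation, peptide mass computation, in-silico tryptic
digestion for mass-spectrometry querying, and conservation shading of
ortholog alignments. A seeded simulator generates circular genomes with
planted altORFs and a truth table, so every claim the pipeline makes can
be checked without downloading anything.

## Genetic codes

Three codes are built in (`loadGeneticCode()`):

* `standard` — the universal nuclear code;
* `vertebrate_mito` — NCBI transl_table 2 (TGA→Trp, ATA→Met, AGA/AGG
  conventionally stops);
* `vertebrate_mito_modified` — transl_table 2 with AGA and AGG read as
  arginine, leaving exactly TAA and TAG as stops. This reflects the
  experimental evidence that human mitochondria terminate only at
  UAA/UAG; AGA/AGG at annotated gene ends are resolved by frameshifting
  rather than termination. This is the default discovery code, and it is
  the single change that most affects ORF counts: restoring AGA/AGG as
  stops fragments many long alternative frames.

DNA (T) is the internal alphabet; RNA input is converted on read. Start
sets default to ATG alone for ATG-anchored scanning (the convention of
ATG-anchored ORF catalogues), with ATG/ATA/ATT available for the
mitochondrial codes where non-ATG initiation is common. Ambiguity codes
are rejected by default; `lenient = TRUE` translates any triplet
containing N as `X` (the human reference mtDNA contains one placeholder
position, so this mode matters in practice).

## The scanning model

`scanOrfs()` treats each strand of a circular genome of length $L$
(with $3 \mid L$, true of the 16,569-nt human reference) as three
disjoint codon cycles. Two modes:

* **stop_to_stop** (default): every maximal stop-free codon run of at
  least `minAa` codons is one ORF. This is the right discovery mode for
  mitochondrial altORF catalogues, whose reported peptides often begin
  with non-methionine residues — a start-anchored scan would never see
  them.
* **atg_initiated**: within each stop-to-stop run, the ORF from the
  5'-most start codon to the run's stop; `allDownstreamStarts = TRUE`
  emits one record per in-frame start, which is how a downstream
  alternative initiation codon inside an annotated gene is surfaced.

Default `minAa = 20` counts coding codons only (60 nt without the stop);
the stop codon is reported separately in `nt_length_with_stop`. Published
ORF tables are not consistent about whether the stop is part of the
printed interval, so records carry both `end_no_stop` and the
stop-inclusive length, and coordinate-sensitive comparisons should pin
the start.

Degenerate but well-defined cases: a wholly stop-free codon cycle is
emitted once, flagged `wraps_origin`, with its canonical start at the
lowest reference position (its phase is a convention; tests that assert
rotation invariance therefore compare such records by count). When
$3 \nmid L$ the codon walk visits every position and each strand has a
single cycle of $L$ codons; the same run logic applies.

Minus-strand records report reference coordinates with
`start > end_no_stop` — the dialect used by published mtDNA candidate
tables for antisense ORFs — while BED/GFF3 exports use standard
strand-explicit intervals, with origin-crossing ORFs split into two
ranges sharing an ID. Frame labels (±1, ±2, ±3) follow a fixed positional
formula; because published figures rarely state their frame-label origin,
all classification logic uses relative frame offsets instead, which are
convention-free.

## Classification

`classifyOrfs()` assigns each ORF the feature with maximal nucleotide
overlap (computed on circular arcs) as host. Same-strand ORFs in a
protein-coding host get `frame_offset = (orf_start - host_start) mod 3`
along the shared strand's 5'→3' axis: 1 or 2 is a sense frameshift, 0 a
same-frame nested record. Opposite strand is `antisense` (no frame is
assigned: antisense overlap is biologically frame-less until a transcript
is shown). ORFs in rRNA/tRNA genes are `within_rRNA`/`within_tRNA` and
are *retained* by `filterUnannotated()` — the known micropeptides live
inside structural RNA genes, so RNA residency is no grounds for removal.

Two genuinely open choices, resolved as follows:

* **Ties.** mtDNA genes abut, so an ORF can straddle a boundary. Only an
  exact tie in overlap yields `multi_feature` (all hosts listed);
  otherwise the larger overlap wins. A proportional-overlap rule was
  rejected because it would make classification sensitive to annotation
  end-convention noise of ±3 nt.
* **D-loop.** The classification vocabulary has no control-region
  category; the D-loop is non-coding, so D-loop-hosted ORFs are reported
  `intergenic` with the host name still recorded.

Known micropeptides are matched by exact peptide string or coordinate
identity from a user-editable sidecar table
(`inst/extdata/known_micropeptides.tsv`); their coordinates are not
hardcoded because published sources disagree on them.

## Peptide masses

Masses are computed from residue elemental compositions, not from a
rounded residue table. Average masses use the IUPAC conventional atomic
weights C 12.0107, H 1.00794, N 14.0067, O 15.9994, S 32.065 — the
vintage used by peptide-synthesis datasheets, which reproduces the
supplier-reported 11,532.06 Da for the 99-residue nd4-internal peptide to
within 0.005 Da. (The 2021 abridged weights shift this by +0.17 Da;
fixing the vintage in code keeps tests bit-stable and matches the
reported values.) Monoisotopic masses use CODATA most-abundant-isotope
masses and drive the MS-facing mass window. Report columns print average
mass in kDa at one decimal, the precision of predicted-MW columns in
candidate tables.

## In-silico digestion

`digestProtein()` models trypsin: cleavage after K/R, never at the
C-terminus, suppressed before proline by default (`prolineRule`), with
peptides spanning up to `maxMiscleavages` consecutive cleavage intervals.
The default filter set — ≤2 missed cleavages, ≥7 residues, 400–6000 Da —
mimics the experimental acquisition range of large MS/MS datasets so that
query lists are neither padded with unobservable peptides nor missing
plausible ones. Mass kind defaults to monoisotopic (the search-engine
convention); both the proline rule and the mass kind are echoed in the
run log because published methods sections usually state neither.

## Conservation shading

`globalAlign()` is Needleman–Wunsch–Gotoh with affine gaps (a gap of
length $k$ costs `gapOpen + (k-1) gapExtend`; defaults +1/−1/−5/−1) and a
deterministic traceback (diagonal, then up, then left). The defaults
favour few compact gaps, appropriate for closely related ortholog
peptides; they are configurable because classic progressive aligners use
different (unpublished, matrix-based) parameters, so gap placement may
legitimately differ between tools. `progressiveMsa()` is a center-star
alignment: the center is the sequence with the highest summed pairwise
identity, pairwise alignments to the center are merged over the center's
gap profile ("once a gap, always a gap"), and row order is preserved.
`conservationTiers()` implements two-tier shading: a column is
`all_conserved` (black in conventional figures) only if gap-free and
unanimous, `near_conserved` (gray) if exactly $n-1$ of $n$ rows agree.
Stop symbols (`*`), accepted as a 21st residue for orthologs read through
a stop, never count as conserved.

## The simulator

`generateGenome()` and `emulateMitoLayout()` exist so that scanning,
classification and filtering can be tested against a known truth. Every
plant — reference gene or altORF — is embedded as
`[in-frame stop][ATG][stop-free body][stop]`, so a rescan recovers it at
exactly its planted coordinates in either mode. Sense-frameshift plants
are placed inside their host at the requested offset, antisense plants on
the opposite strand, and all simultaneous frame constraints (the host
frame must stay stop-free through the planted region) are satisfied by
constraint repair: free positions are drawn from the background base
composition (default A 30 / T 25 / C 25 / G 20 %, i.e. mtDNA-like
A+T ≈ 55 %) and locally resampled until no constrained codon is a stop,
with bounded sweeps and an error naming the offending plant when a
configuration is genuinely infeasible.

Background is drawn codon-wise in frame 1 at a requested stop density
(default 0.05, close to the uniform-random rate of 2/64–4/64). Stop
density in the *other* frames of random sequence is low enough that long
spurious ORFs are common — exactly as in real mtDNA, where a six-frame
scan of 16.5 kb yields a couple of hundred ≥20-aa ORFs. When plants are
present the generator therefore also *suppresses* spurious runs: stop
codons are inserted into every frame outside the planted ORFs until no
stop-free run of ≥ `suppressAa` (default 20) codons remains, each
insertion checked against all plant constraints. With suppression on,
the truth table is the complete ORF catalogue at that cutoff, which is
what makes "the filter returns exactly the planted records" a testable
statement.

`emulateMitoLayout()` arranges 13 genes (one minus-strand, as for human
ND6), 2 rRNAs, 22 tRNAs and a D-loop head-to-tail with 4-nt spacers
(~16.9 kb, 38 annotations) and plants six altORFs spanning every kind:
sense frameshifts at offsets 1 and 2, an antisense ORF, rRNA- and
tRNA-resident ORFs, and an intergenic ORF in a 200-nt gap.

What the simulator does *not* emulate — and what passing tests therefore
do not show about real data: realistic codon usage and strand-asymmetric
base composition, overlapping reference genes (human ATP8/ATP6 share
sequence), incomplete stop codons completed by polyadenylation, NUMT
confounders, and sequencing ambiguity. Recovery statistics on simulated
genomes validate the *logic* of scanning and classification, not the
biological ORF count of any particular genome.

## Numerical and testing choices

* All randomness is seed-controlled; the simulator saves and restores the
  caller's RNG state. Identical seeds give byte-identical genomes and
  reports; distinct seeds differ.
* Scan correctness is established against an independent brute-force
  oracle (per-position run detection) on random circular genomes of up to
  300 nt, including lengths not divisible by 3; digestion against
  exhaustive substring enumeration on proteins of up to 200 aa; alignment
  scores against exhaustive path enumeration on peptides of up to ~8
  residues. The test suite runs 100 random genomes and 100 random
  proteins in the oracle comparisons and 50 simulator seeds in the
  recovery property — sizes chosen to exercise every branch (wrapping,
  both strands, both modes, both proline-rule settings) while keeping the
  suite fast on a laptop.
* Reproducing the published human-mtDNA catalogue (249 ORFs of ≥ 20 aa;
  227 after removing the 13 genes and 9 named micropeptides; the
  nd4-internal ORF at 11,557 with frame offset 2) requires the NC_012920
  reference FASTA and its gene annotation, which this package does not
  redistribute; the corresponding acceptance test documents the expected
  numbers and reports failure until those files are supplied under
  `inst/extdata/`. Exact count parity additionally depends on two
  documented scan-definition flags (whether the stop codon counts toward
  the length cutoff, and the start-codon policy), which the run log
  always echoes.

## Known limitations

Frame labels are package conventions; only relative offsets are
comparable across tools. The scanner does not collapse nested ORFs beyond
the stated start-selection rules, does not score initiation context, and
does not integrate ribosome-profiling evidence. The aligner is for
desk-scale ortholog sets (tens of sequences), not genome-scale MSA.
Digestion models cleavage specificity only — no PTMs, charge states or
spectra; spectrum matching is the job of downstream search tools that
consume the exported peptide lists.

```{r worked, eval = FALSE}
# A five-line discovery run on the simulated mitogenome:
sim <- emulateMitoLayout(seed = 7)
res <- runDiscovery(runConfig(sim$genome, sim$annotations))
res$candidates[, c("aa_length", "predicted_mw_kda", "position", "category")]
```
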