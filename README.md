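# mtaltorf

Discovery of alternative open reading frames (altORFs) in circular
mitochondrial genomes.

## The problem

The human mitogenome is a 16.5-kb circle annotated with only 37 genes,
packed head-to-tail. But reading frames overlap: an ORF can hide inside
an annotated gene in a shifted sense frame, on the antisense strand, or
inside an rRNA/tRNA gene — and several such mitochondrial micropeptides
(Humanin, SHLP1–6, MOTS-c, SHMOOSE, and the 99-residue peptide encoded
inside *nd4*) are biologically active. Finding these candidates is a
sequence-analysis problem with sharp conventions: a circular genome has
six reading frames that wrap the origin; vertebrate mitochondria use a
non-standard genetic code, and whether AGA/AGG are read as stops or as
arginine decides how many long alternative frames exist at all; and
candidate peptides must be turned into tryptic query lists before any
mass-spectrometry evidence can be sought.

`mtaltorf` is for researchers who want to run that discovery procedure —
on the human mitogenome, another mitogenome, or a synthetic benchmark —
as a reproducible pipeline rather than a one-off script.

## What it computes

* **Six-frame circular ORF enumeration** (`scanOrfs`), in two modes:
  *stop-to-stop* (every maximal stop-free codon run of ≥ `minAa` codons;
  peptides may begin with any residue) and *ATG-initiated* (optionally
  one record per in-frame start codon, surfacing downstream alternative
  initiation inside genes). Under the modified vertebrate mitochondrial
  code (`vertebrate_mito_modified`: transl_table 2 with AGA/AGG → Arg,
  stops exactly {TAA, TAG}).
* **Overlap classification** (`classifyOrfs`, `filterUnannotated`):
  host assignment by maximal circular overlap; categories
  `matches_reference`, `sense_frameshift` (with frame offset
  (orf−host) mod 3 on the shared strand), `antisense`, `within_rRNA`,
  `within_tRNA`, `intergenic`, `multi_feature`.
* **Peptide masses** (`averageMass`, `monoisotopicMass`,
  `peptideProfile`) from residue elemental composition.
* **In-silico trypsin digestion** (`digestProtein`, `digestPeptides`):
  ≤ 2 missed cleavages, ≥ 7 residues, 400–6000 Da by default, proline
  rule on — an MS-ready query list.
* **Conservation shading** (`globalAlign`, `progressiveMsa`,
  `conservationTiers`): affine-gap global alignment, center-star MSA,
  and the black/gray two-tier column shading (conserved in all rows /
  in all but one).
* **A seeded simulator** (`generateGenome`, `emulateMitoLayout`) that
  plants reference genes and altORFs of every kind into a circular
  genome and returns a truth table, so the whole pipeline is testable
  offline.

## Worked example

A full discovery run on the simulated mitogenome (13 genes, 2 rRNAs,
22 tRNAs, D-loop, six planted altORFs):

```r
library(mtaltorf)
sim <- emulateMitoLayout(seed = 7)
res <- runDiscovery(runConfig(sim$genome, sim$annotations))
res$candidates[, c("aa_length", "predicted_mw_kda", "position", "category")]
#>  aa_length predicted_mw_kda                                    position         category
#>         40              4.5              cox3 anti-sense 10136 to 10017        antisense
#>         24              2.9                    Within rrnL 2842 to 2913      within_rRNA
#>         28              3.1   Within nd2 sense, frameshift 5345 to 5428 sense_frameshift
#>         22              2.7                   intergenic 16766 to 16831       intergenic
#>         20              2.5                   Within trnL1 3783 to 3842      within_tRNA
#>         33              3.5 Within nd4 sense, frameshift 12282 to 12380 sense_frameshift
```

The scan found exactly the six planted altORFs (the 13 reference genes
were recognised as `matches_reference` and removed); positions are
printed in the candidate-table dialect, with antisense ORFs reported
start > end on the reference.

Peptide properties of the published 99-residue nd4-internal peptide
(shipped in `inst/extdata/published_candidate_peptides.fasta`):

```r
fa <- system.file("extdata", "published_candidate_peptides.fasta", package = "mtaltorf")
peps <- Biostrings::readAAStringSet(fa)
peptideProfile(as.character(peps[["MTALTND4"]]))
#>   aa_length average_mass monoisotopic_mass mass_kda_1dp
#> 1        99     11532.07          11525.02         11.5
```

and its tryptic query list (28 peptides under the default MS filters):

```r
digestProtein(as.character(peps[["MTALTND4"]]), digestParams())
#>  parent_id       aa_sequence start_in_parent miscleavages      mass
#>    protein           MRHNYNK               1            1  961.4552
#>    protein MRHNYNKLHLPTTNRPK               1            2 2119.1221
#>    protein   HNYNKLHLPTTNRPK               3            1 1831.9805
#>    ...
```

To run on a real genome, point `runConfig` at a single-record FASTA and
a GFF3 annotation:

```r
res <- runDiscovery(runConfig("mtDNA.fasta", "mtDNA.gff3", outDir = "out"))
```

which writes `candidates.tsv`, `peptides.fasta`, `orfs.bed`,
`orfs.gff3`, `digest.tsv`, `peptide_list.txt` and a `run.log` recording
every defaulted parameter.

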