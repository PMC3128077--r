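---
title: "Finding the hidden subunit IIa of B-family oxidases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding the hidden subunit IIa of B-family oxidases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iiascout)
```

## The scientific problem

B-family (*ba*~3~-type) heme-copper oxidases were long described as
two-subunit enzymes: a 12-helix catalytic subunit I and a small subunit
II carrying the Cu~A~ electron-entry site. Crystallography of the
*Thermus thermophilus* enzyme revealed a third, tiny component —
"subunit IIa", a single transmembrane helix of only ~34–78 residues
that structurally replaces the N-terminal helix that subunit II
possesses in A-family oxidases. Genes this small are routinely missed
by automatic genome annotation, and the proteins themselves evade
standard proteomics: they are too hydrophobic and too small to resolve
on gels or to yield tryptic peptides.

`iiascout` implements the complete discovery pipeline for such
subunits as reusable, tested components:

1. **Micro-ORF scanning** (`upstream_window()`, `scan_small_orfs()`)
   in the window directly 5′ of the subunit-II ("anchor") gene, the
   conserved operonic location of subunit-IIa genes.
2. **Transmembrane candidacy filtering** (`call_tm_segments()`,
   `is_candidate_iia()`): a candidate must carry exactly one predicted
   membrane-spanning segment.
3. **Frameshift correction** (`detect_frameshift()`): single-nucleotide
   sequencing errors can split or truncate genes; a deletion that fuses
   a much longer reading frame flags the error.
4. **Motif and alignment validation** (`scan_motif()`,
   `pairwise_identity_similarity()`): the conserved P-x(1–3)-G-[TA]
   motif and tryptophan, and identity/similarity against a known
   subunit IIa.
5. **Mass-spectrometric corroboration** (`peptide_mass()`,
   `mz_of_species()`, `assign_peaks()`, `tryptic_digest()`,
   `pmf_coverage()`, `fragment_mz_series()`, `read_ladder()`).
6. **A cross-genome survey report** (`survey_genome()`,
   `tabulate_survey()`), in the shape of the published 36-genome
   comparison table shipped in `inst/extdata/table1_survey.tsv`.
7. **Synthetic data with known truth** (`simulate_operon_genome()`,
   `simulate_spectra()`), so every stage is testable at desk scale.

## Coordinates, translation and ORF scanning

All genomic coordinates are 1-based inclusive on the forward strand
(GFF3 convention); minus-strand work happens by handing
reverse-complemented regions to the scanners. Translation uses NCBI
genetic-code table 11 (bacteria/archaea) and is deliberately literal:
stop codons render as `*` (the caller decides about truncation),
codons containing `N` render as `X` and disqualify downstream mass
computation, and start codons are translated by the table (a GTG start
reads as Val), since the true initiator residue of an unannotated gene
is not knowable from sequence alone.

`scan_small_orfs()` reports, per frame, every ORF that begins with an
allowed start codon (default ATG/GTG/TTG — common bacterial starts;
the source operons do not pin down the start codon), ends at an
in-frame stop, and encodes 25–100 residues (bracketing the observed
34–78 aa range of subunit-IIa genes). ORFs sharing a stop codon keep
only the longest start by default; ORFs running off the window edge
are flagged `open_ended` and excluded from candidacy, because an
unterminated reading frame is not a gene model. The scanner is tested
frame-by-frame against an independent brute-force enumerator on random
regions up to 2 kb.

The upstream window defaults to 750 nt, comfortably covering the
~720 nt intergenic region in which the founding unannotated example
sits, and is truncated at the nearest annotated same-strand gene so
that the scan cannot wander into a neighboring coding region.

## Transmembrane calling

`call_tm_segments()` is a windowed Kyte–Doolittle hydropathy caller:
window 19 residues (the canonical single-helix span), call threshold
1.6 (mean hydropathy, dimensionless), minimum merged segment 15
residues. A segment is the union of the residues covered by a maximal
run of at-or-above-threshold windows; overlapping unions merge. The
reported `mean_hydropathy` is the mean over the segment's
above-threshold windows, so it is by construction at or above the
threshold. These are standard single-helix heuristics; they are not a
re-implementation of an HMM-based topology predictor, and helix counts
for large polytopic proteins (such as subunit I) are outside what this
caller is expected to reproduce.

Two behavioral notes that matter for interpretation:

* The called span extends beyond the hydrophobic core by up to
  `window − k` residues on each side, where `k` is the minimum number
  of hydrophobic residues a window needs to clear the threshold
  (k = 14 for a pure-Leu core against Glu flanks). Two 19-residue
  cores are therefore guaranteed to yield two separate segments only
  when separated by enough hydrophilic residues — about 10 for
  Leu-only cores, about 13 for hotter Leu/Ile cores. Closer cores
  merge into one call, which is the honest answer of a windowed
  method at this resolution.
* Non-standard residues score 0 with a warning.

`is_candidate_iia()` applies the published candidacy rule: exactly one
transmembrane segment and a length within [25, 100] residues, with the
failing criterion named in the returned reason.

## Frameshift detection

`detect_frameshift()` asks, for every homopolymer run in a region,
whether deleting one base (optionally: inserting one) would fuse a
substantially longer open reading frame across the site — the
signature of a single-nucleotide error in the deposited sequence. The
design choices here were the least constrained by precedent and are
worth recording:

* **Closed ORFs only.** Open-ended reading frames (no stop before the
  region edge) are excluded from scoring; otherwise the measured gain
  depends on where the analysis window happened to be cut.
* **Baseline = the 5′ partial.** A frameshift splits a gene into
  partial ORFs. The 3′ partial often reaches far back through a
  stop-free shifted phase, so "the longest ORF covering the site"
  over-states the pre-edit situation precisely at the true site. The
  score is instead `fused ORF length − length of the original ORF
  sharing the fused ORF's start codon` — the extension gained by the
  gene model that begins at that start. When no original ORF shares
  the start, the longest original ORF covering that position is used.
* **Indistinguishability is reported, not hidden.** All single-base
  indels within one homopolymer run produce the same edited sequence,
  so each run yields one call. Moreover, edits in *adjacent* runs are
  also indistinguishable whenever the re-read stretch between them
  contains no stop codon (the fused ORF has identical span and
  length); such calls merge into a single call spanning those runs.
  The reported interval is the honest localization limit of a
  length-based method — the original discovery likewise pinned the
  exact position by re-sequencing, not by ORF arithmetic.
* The default minimum gain is 20 residues (60 nt), large enough that
  chance rearrangements of stop codons do not qualify.

## Mass spectrometry

Masses are computed from residue elemental compositions (IUPAC
monoisotopic masses and standard atomic weights, stored once as
package data): peptide mass = residues + one water. Monoisotopic mode
corresponds to resolved reflectron-mode MALDI peaks; average mode to
linear-mode intact-protein peaks. The implementation is tested to
10⁻⁴ Da against an independently coded oracle that sums free
amino-acid formulas and removes waters.

`mz_of_species()` builds singly charged species hypotheses (MALDI
context; all corroborating species in the source data are z = 1):
proton 1.007276 Da or sodium cation 22.989218 Da as charge carrier,
−17.026549 Da per NH₃ neutral loss, +42.010565 Da per acetyl adduct.
`assign_peaks()` enumerates carrier × loss × adduct combinations (each
modification at most once by default) over all candidates, accepts
matches within a ppm tolerance (default 150 ppm, covering the ~50–100
ppm deviations typical of externally calibrated spectra), and flags
the best assignment per peak by |Δppm|.

`tryptic_digest()` cleaves C-terminal to Lys/Arg with the standard
proline suppression rule and emits peptides with up to a configurable
number of missed cleavages; `pmf_coverage()` matches observed [M+H]⁺
masses at 50 ppm (typical reflectron PMF) and reports the covered
fraction of the parent plus whether any match falls in a designated
N-terminal interval — the key evidence when an annotation is missing
an N-terminal extension.

`fragment_mz_series()` produces b/y ladders; `read_ladder()` reads a
residue sequence out of consecutive y-ion mass differences at a 0.5 Da
tolerance (a manual low-resolution TOF/TOF read). At that tolerance
Ile/Leu are always indistinguishable and Lys/Gln (Δ = 0.036 Da)
effectively so; readouts therefore carry ambiguity sets (`I/L`, `K/Q`)
rather than guesses. The lowest peak is additionally interpreted as a
candidate y₁ ion so the C-terminal residue itself can be read; when
that anchoring succeeds, reported positions are true indices from the
C-terminus.

## The synthetic-data generator

`simulate_operon_genome()` emulates the conserved gene arrangement:
a planted micro-ORF (default 41 aa, within the observed 34–78 aa
range) with one 19-residue hydrophobic core, the P-x(1–3)-G-[TA] motif
around position 12 and a conserved Trp near the C-terminus, sitting in
an intergenic region ~120 nt upstream of a 150-aa anchor gene with one
(optionally two) hydrophobic core(s); optionally a single-base
insertion inside the anchor gene. A truth object records every planted
coordinate and peptide. `simulate_spectra()` produces an MS1 peak list
with the protonated base species plus −NH₃ and +acetyl satellites
under ~80 ppm calibration jitter and well-separated noise peaks, and
an MS/MS y-ladder.

The generator is engineered so that planted truth is *identifiable*,
not merely present — the properties below are design guarantees, and
deviating from them voids the recovery invariants the test suite
asserts:

* **Cores** alternate Leu/Ile encoded as CTA/ATT. The +1 reading phase
  of such a core is a wall of TAA stops and the +2 phase reads
  hydrophilic Asn/Ser, so no frame-shifted reading of a core can form
  a competing transmembrane ORF. Two cores are separated by 14
  hydrophilic residues so their called spans stay disjoint.
* **Flanks** draw from Glu/Lys/Gln only. Ser is hydrophilic but weak
  enough to stretch called segments; Asp/Asn codons end in "AT" and
  read as Ile/Met in shifted phases, which can assemble spurious
  hydrophobic stretches. The GAA/AAA/CAA codons read as
  Lys/Asn/Arg/Thr in every shifted phase and contain no start codon.
* **Non-genic sequence** (background and intergenic spacer) is random
  DNA tiled every 24 nt with `TAAATAAATAA`, which carries stop codons
  in all three frames: no reading frame can run stop-free through
  non-genic sequence for more than ~13 codons, so it can neither host
  a ≥25-aa candidate nor lend hydrophobic stretches to read-through
  ORFs. In-frame stops are also placed immediately 5′ of the planted
  ORF so upstream read-through cannot absorb it into a longer gene
  model.
* **MS/MS error** has two components, as on a real TOF instrument: a
  slowly varying linear calibration drift (amplitude 0.35 Da, shared
  by neighboring peaks) plus a peak-wise uniform ±0.15 Da term. Peak
  deviations reach ~0.5 Da, but the drift cancels in consecutive
  differences, so ladder steps stay within the 0.5 Da reading
  tolerance. An uncorrelated ±0.3 Da model is available by setting
  the drift amplitude to zero; with it, step errors up to 0.6 Da
  occasionally alias Gln to Glu, which no reader can resolve — a
  useful stress condition but not a recovery guarantee.
* A single seeded RNG drives each invocation, the caller's RNG state
  is restored afterwards, and a fixed seed yields byte-identical
  FASTA/GFF/JSON output.

What the generator does **not** emulate: realistic codon usage or GC
content, isotopic envelopes, charge states above 1, peak intensities
with physical meaning, or chimeric/contaminant spectra. Passing the
planted-truth suite therefore demonstrates the correctness of the
pipeline's logic under clean, identifiable conditions — it does not
certify performance on real genomes, where candidate filtering
inherits the error rates of hydropathy-based TM prediction.

## Alignment conventions

`pairwise_identity_similarity()` is a global Needleman–Wunsch
alignment under BLOSUM62 with affine gaps (opening 10, extension 0.5),
delegated to `Biostrings::pairwiseAlignment()` and cross-checked in
the tests against a brute-force enumeration of all alignments of short
strings. Identity and similarity percentages use the full alignment
length (gap columns included) as denominator, and "similar" means the
classic ClustalW strong conservation groups — the published 30%/60%
identity/similarity figures for the founding pair were produced with
an unstated convention, so these choices are declared rather than
fitted, and those two figures are treated as indicative only.

## The survey and its packaged reference table

`survey_genome()` reproduces the per-genome decision procedure: the
anchor's peptide yields its TM count and average-mode theoretical mass
(the convention of the mass tool used for the published table); an
annotated upstream gene passing the candidacy filter gives status
`annotated`; otherwise the upstream window is scanned and a passing
micro-ORF gives `detected_unannotated` (the candidate closest to the
anchor wins if several pass); otherwise `absent`.
`tabulate_survey()` emits the report in the published column order and
enforces the partition invariant `regions = annotated + detected +
absent`. The packaged transcription of the published 36-genome table
reproduces its counts — 36 regions, 21 accessioned subunits IIa, 6
unannotated detections, 9 absences — and its structural observation
that subunit IIa co-occurs exactly with single-helix subunits II.
Re-running the survey on the real genomes requires locally provided
sequence files (the package never downloads) and is deliberately kept
out of the test suite.

## Problem sizes and numerical choices

The test suite validates: mass arithmetic against the published
printed values; 1,000 random peptides against the elemental-mass
oracle (10⁻⁴ Da); ORF scanning against brute force on random regions
up to 2 kb; ladder readback on 1,000 exact and 200 jittered spectra;
and end-to-end planted-truth recovery (ORF, classification, frameshift
run, MS1 species, y-ladder) on 20 seeded genome/spectrum conditions
spanning candidate lengths 34–78 aa. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch
under a caller-provided seed. Ties in ORF selection are broken by
proximity to the anchor, then length; ties in frameshift ranking by
score, then leftmost position. Degenerate inputs (empty windows,
regions shorter than the scan minimum, peptides shorter than the
hydropathy window, empty peak lists) return typed empty results with a
message rather than errors wherever the empty answer is scientifically
meaningful.

## Known limitations

* The TM caller is a hydropathy heuristic; it will not reproduce
  HMM-based helix counts for polytopic proteins and is not a topology
  predictor.
* Frameshift localization is limited to an indistinguishability
  interval; exact positions require re-sequencing.
* The ladder reader handles singly charged y ions only, and reports
  ambiguity sets at its working tolerance rather than forcing calls.
* The survey trusts annotation IDs for the anchor gene and considers
  only the contiguous upstream window (an intervening gene between
  subunit IIa and subunit II, as occurs in one published genome, stops
  the search at that gene).
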