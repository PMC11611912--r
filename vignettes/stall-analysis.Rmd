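---
title: "Detecting translational stalling from ribosome footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting translational stalling from ribosome footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribostall)
```

## The problem

During elongation, bacterial ribosomes pause at certain sequence contexts —
most prominently at polyproline-containing XP(P)X motifs, where peptide-bond
formation is slow.  Elongation factor P (EF-P) and its paralog EfpL rescue
such stalled ribosomes; in deletion strains the pauses persist and can be
read out by ribosome profiling: nuclease-protected 20–40 nt footprints mark
where ribosomes sat, and a codon-resolution occupancy map shows where they
dwelled.

`ribostall` implements the complete desk-side analysis for this experiment:
raw-read decomposition and UMI deduplication, contaminant filtering and
unique mapping, A-site assignment, occupancy profiles and metagene curves,
sliding-window pause calling, E/P/A-site trimer enrichment, E-site codon
nucleotide bias, asymmetry scores with factor-dependency calls, and a
sequence classifier separating EF-P from EfpL family members.  A footprint
simulator with planted stall motifs supplies ground-truth libraries so every
stage can be validated quantitatively.

## Read model and preprocessing

Raw reads follow the library layout

```
QQQ — footprint — NNNNN — BBBBB — adapter
```

with three untemplated 5' additions, a 5-nt UMI, a 5-nt sample barcode and a
fixed 3' adapter.  `decompose_reads()` removes the untemplated bases, trims
at the first exact adapter occurrence (a trailing partial adapter is also
trimmed), discards reads without an adapter hit and reads whose trimmed
remainder is shorter than 30 nt (so footprints are at least 20 nt), and
splits the remainder from the 3' end.  Adapter matching is exact: the
simulator produces error-free reads, and the package documents this as a
deliberate simplification rather than emulating a particular trimmer's
error-tolerance heuristics.

`dedup_umi()` collapses PCR duplicates on the (UMI, fragment sequence) pair,
keeping first occurrences in input order.  Using the fragment as part of the
key avoids collapsing distinct molecules that happen to share a UMI; the
converse failure mode — two independent molecules with identical position,
length *and* UMI — is rare but real (with a 5-nt UMI and 21 possible lengths
there are ~21,500 distinguishable duplicates per A-site position) and is the
reason deduplicated counts at very strong stall sites sit a few percent
below truth.

## Occupancy and the A-site offset

Footprints are matched to the transcriptome by exact substring search on
both strands; only fragments with exactly one occurrence anywhere are kept,
mirroring unique-mapping alignment policy.  Coordinates are 0-based
half-open internally, with codon indices 0-based from the initiator; SAM
input/output converts to and from 1-based positions.

The ribosome's A-site nucleotide is placed a fixed `offset` upstream of the
footprint's 3' end (default 11 nt, measured along the read's 5'→3'
direction).  The offset is a per-library calibration, so it is a parameter
everywhere, not a constant.  Reads whose A site falls outside the CDS are
excluded and tallied; reads whose A site lands in the stop codon are
retained at the terminal codon index.  Bookkeeping is exact at every stage:
raw = rejected + footprints; footprints = duplicates + deduplicated;
deduplicated = contaminant + unmapped + multimapped + mapped; mapped =
out-of-CDS + retained.

`metagene()` rescales each gene's codon counts to mean 1 before averaging,
so highly expressed genes do not dominate; it is used to confirm that a
perturbation affects elongation rather than initiation or termination.

## Pause score

For a CDS nucleotide position $i$ with count $x_i$ and window lengths
$w_1, w_2$ (defaults: both 1000 nt), the per-window fold change is

$$ f_w(i) = \frac{x_i}{\operatorname{mean}\{x_j : j \in W_w(i),\, j \ne i\}} $$

where $W_w(i)$ is the window of $w$ nt centred on $i$
($[i-\lfloor w/2\rfloor,\ i+\lceil w/2\rceil-1]$), clipped to the gene.  The
pause score is $(f_{w_1} + f_{w_2})/2$ and is defined only where both window
means are positive.  Excluding the focal position from the mean makes a flat
profile score exactly 1.0 at every position and makes the constructed
example — background 2 everywhere, 40 at the focal position — score exactly
20.  Coverage is the fraction of positions with at least one read in the
larger clipped window (focal position included); a site is called when
score ≥ 20 and coverage ≥ 5%, both parameters.

Two numerical choices are worth stating.  First, both windows are *centred*;
with two equal default lengths the two fold changes coincide, and the
two-window structure matters only when users set different lengths.  Second,
adjacent super-threshold positions are reported individually by default;
`merge_adjacent = TRUE` collapses each run to its maximum (first position on
ties).  A brute-force loop implementation in the test suite pins these
definitions to 1e-9.

The score is scale invariant (multiplying a profile by $k>0$ changes
nothing) and monotone in the focal count — both properties are tested.

## Motif statistics

**Trimer enrichment.**  Each pause site is annotated with the amino acids in
the ribosome's E, P and A sites (codons $a-2, a-1, a$ for A-site codon $a$);
sites with $a < 2$ or a stop in the window are skipped.  Pause frequency is
the unweighted fraction of sites carrying a trimer (each called site counts
once).  The background frequency is *occupancy-weighted*: every
trimer-defined A-site position contributes its codon count, so the
denominator is what ribosomes actually covered, not transcript composition.
Enrichment is the ratio; trimers seen at pause sites but absent from the
background are flagged rather than given a finite score.

**E-site codon bias.**  For sites with $a \ge 2$ the codon at $a-2$ is
tallied per position into a 4 × 3 nucleotide frequency matrix; the
first-position guanosine fraction is reported separately because a G-starting
E-site codon is the hallmark signal of factor-dependent arrest motifs.

**Asymmetry score.**  For a motif spanning codons $[s, e)$,

$$ \mathrm{AS} = \frac{\sum \text{downstream flank} + \alpha}
                      {\sum \text{upstream flank} + \alpha} $$

with the motif span excluded from both sums, flanks of $F$ codons clipped to
the CDS, and a pseudocount $\alpha$.  Defaults $F = 25$ and $\alpha = 0.5$
are design choices — large enough flanks to average out single-codon noise,
small enough to stay local to the motif — and are parameters everywhere.
AS < 1 means ribosomes fail to make it past the motif.

**Dependency.**  With asymmetry scores from a wild type and a
factor-deletion strain, `dependency_call()` labels a motif `DEPENDENT` when
$\mathrm{AS}_{mut} \le \mathrm{AS}_{wt}/\theta$, `INDUCED` when
$\mathrm{AS}_{mut} \ge \theta\,\mathrm{AS}_{wt}$ (the factor itself caused
the pause), and `INDEPENDENT` otherwise ($\theta = 2$ by default).

## The simulator and what it does (and does not) emulate

`make_transcriptome()` builds independent transcripts: a 60-nt flank, ATG,
random sense codons, a stop codon, a 60-nt flank.  The flanks are a
geometric necessity — a 40-nt footprint whose 3' end lies 11 nt downstream
of the A site of codon 0 reaches 28 nt upstream of the CDS — and 60 nt
covers every codon for the default geometry.  Planted motifs overwrite the
E/P/A codons with synonymous codons for the requested trimer, honouring an
optional constraint on the E-site codon's first nucleotide (the constraint
must be satisfiable within the genetic code: no proline codon starts with
G).

`simulate_footprints()` draws each read's A-site codon multinomially with
probability proportional to a dwell time: baseline 1, multiplied by $s$ at a
planted stall codon, and by $1-d$ at every codon downstream of a drop-off
motif.  Read lengths are uniform over 20–40 nt (the gel cut is the only
constraint the experiment imposes, so uniform is the assumption of least
structure), 3' ends sit exactly `offset` nt downstream of the A site, and
with probability `dup_rate` a read gains one identical PCR duplicate.
Qualities are constant `I` (nothing downstream uses them) and the barcode is
fixed per sample (libraries arrive demultiplexed).  Identical configurations
give byte-identical output.

The simulator deliberately omits sequencing errors, nuclease sequence bias,
non-uniform footprint-length distributions, rRNA contamination (a
contaminant FASTA can be supplied separately) and ribosome queuing upstream
of stalls.  Passing tests therefore demonstrate the *analysis* is correct
under the stated generative model, not that the model captures every
property of real libraries.

### A consequence of the memoryless drop-off model

Because drop-off is modelled as a downstream density scale factor rather
than per-ribosome traffic, the expected asymmetry score at a planted motif
in the deletion strain is simply $1-d$, independent of the stall strength
$s$ (the stall peak itself lies inside the excluded motif span, and without
queuing the upstream flank is unchanged).  A `DEPENDENT` call at threshold
$\theta$ therefore requires $d \ge 1 - 1/\theta$ — at $\theta = 2$, a
drop-off probability of at least 0.5.  The benchmark study below plants
$d = 0.3$, so its motif genes sit at an asymmetry ratio of ≈ 0.7 and are
labelled `INDEPENDENT` by design of the model; the package reports this
honestly rather than inflating $d$ or relaxing $\theta$.  Users simulating
strong aborters (e.g. $d = 0.5$–0.8) will see `DEPENDENT` calls with full
sensitivity.

## The benchmark study

`run_stall_study()` wires everything together under fixed conditions chosen
to be realistic for a bacterial profiling experiment while staying
desk-sized: 20 genes × 300 codons at 50 reads per codon (~360,000 raw reads
per library including 20% duplicates), ten genes carrying one planted motif
each ($s = 50$, $d = 0.3$ in the deletion strain; $s = 1$, $d = 0$ in the
wild type, where the factor neutralizes the stall) and ten motif-free
controls.  Eight motifs have G-starting E-site residues (D, G, V, E) and two
do not (P, K), so the planted first-position G fraction is 0.8.  Both
libraries are round-tripped through FASTQ before processing.  On one CPU the
study runs in well under a minute.

With the default thresholds the study recovers all ten planted sites at
their exact A-site nucleotide, calls nothing on control genes, ranks a
planted trimer top of the enrichment table, and reproduces the planted
E-site G fraction exactly.

## Loop classification

The KOW-domain β3Ωβ4 loop distinguishes the two factor families: canonical
EF-P has a 7-residue loop (`KPGKGQA` in *E. coli*) with the modified lysine
at its tip, while EfpL has an extended loop (`SPTARGAAT`) with an apical
arginine.  `locate_loop_columns()` finds the alignment columns of the loop
from a reference row, `extract_loop()` reads any row's ungapped loop, and
`classify_loop()` applies the rule: more than 7 residues *and* an R tip →
`EFPL`; 1–7 residues → `EFP`; otherwise `OTHER`.  The tip is operationalized
as the middle residue $\lceil L/2 \rceil$, which recovers both documented
anchors (K in `KPGKGQA`, R in `SPTARGAAT`); since "tip" has no universal
positional definition, this choice is stated rather than hidden.  The
classifier is a pure function of the loop string — row order and gap-column
placement cannot change a label, which the test suite checks by
construction.

`example_kow_msa()` (also shipped as
`inst/extdata/synthetic_kow_msa.fasta`) carries the two documented *E. coli*
loops on synthetic scaffold rows for demonstrations and validation; it is
not a biological alignment.

## Known limitations

* Mapping is exact-match unique; reads with sequencing errors would be lost
  rather than rescued with mismatch tolerance.  External aligner output can
  be supplied as SAM instead.
* The pause score has no significance model; it is a fold-change screen, and
  downstream counts (not p-values) should carry inference.
* The asymmetry score reflects drop-off only under the memoryless model;
  queuing ribosomes in real data shift density upstream and can deepen the
  observed asymmetry beyond $1-d$.
* The loop classifier assumes its input alignment already contains KOW-like
  domains; domain detection and alignment construction are out of scope.
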