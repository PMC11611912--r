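# ribostall

Detection and characterization of translational stalling from bacterial
ribosome-profiling (Ribo-seq) footprint libraries, plus sequence
classification of the elongation factors that resolve it.

Ribosomes pause at arrest-prone XP(P)X motifs — proline in the peptidyl
site, flanked by variable residues — unless rescued by elongation factor P
(EF-P) or its paralog EfpL. `ribostall` is for researchers analysing such
experiments: it takes raw footprint reads (layout
`QQQ—footprint—UMI—barcode—adapter`), and produces codon-resolution
occupancy profiles, pause-site calls, stall-motif statistics and
factor-dependency labels, with exact read-count bookkeeping at every stage.
A built-in simulator generates footprint libraries with planted stalls and
known truth so the whole pipeline is quantitatively verifiable.

## The methods at its core

* **A-site assignment.** A footprint's A-site nucleotide sits a fixed
  offset upstream of its 3' end (default 11 nt); codon index =
  ⌊(A-site − CDS start)/3⌋.
* **Pause score.** For position *i* and window length *w* (two windows,
  default 1000 nt each), *f<sub>w</sub>(i)* = count(*i*) / mean count over
  the *w*-window centred on *i* (clipped to the gene, focal position
  excluded); score = mean of the two fold changes. A site is called when
  score ≥ 20 and ≥ 5% of window positions are covered.
* **Trimer enrichment.** Frequency of each E/P/A-site amino-acid trimer
  among pause sites, divided by its ribosome-occupancy-weighted frequency
  over all covered positions.
* **Asymmetry score (AS).** (downstream flank sum + α) / (upstream flank
  sum + α) around a motif (flank 25 codons, α = 0.5); low AS means
  ribosomes rarely make it past. Comparing deletion strain to wild type at
  fold threshold θ = 2 yields `DEPENDENT` / `INDEPENDENT` / `INDUCED`
  labels.
* **Loop classifier.** From a KOW-domain alignment, the β3Ωβ4 loop is
  extracted via reference coordinates (`KPGKGQA`, the canonical 7-residue
  EF-P loop); sequences with a loop longer than 7 residues and an arginine
  at the tip are labelled `EFPL`, 1–7-residue loops `EFP`, others `OTHER`.

## Worked example

Simulate three 100-codon genes at depth 20 with one planted stall (trimer
PPN, 50-fold dwell, 50% drop-off) and run the full pipeline:

```r
library(ribostall)

cfg <- sim_config(n_genes = 3, gene_len_codons = 100, depth = 20,
                  dup_rate = 0.2, seed = 7,
                  planted_motifs = list(list(gene = "g1", codon_index = 50,
                                             trimer = "PPN", s = 50, d = 0.5)))
genes <- make_transcriptome(cfg)
sim <- simulate_footprints(genes, cfg)
write_footprints_fastq(sim, "reads.fastq")

run <- footprints_to_profiles("reads.fastq", genes)
run
#> footprint processing run
#>   raw_reads      7215
#>   no_adapter     0
#>   too_short      0
#>   malformed      0
#>   footprints     7215
#>   umi_duplicates 1238
#>   after_dedup    5977
#>   contaminant    0
#>   unmapped       0
#>   multimapped    0
#>   mapped         5977
#>   out_of_cds     0
#>   retained       5977
```

All 7215 raw reads decompose cleanly; 1238 (UMI, fragment) duplicates are
collapsed (the 1215 injected PCR copies plus 23 coincidental collisions)
and every remaining footprint maps uniquely. Pause calling finds exactly
the planted site — A-site codon 50, i.e. CDS nucleotide 150 — at 184-fold
enrichment:

```r
call_pauses(run$profiles)
#>   gene_id nt_position asite_codon    score  coverage
#> 1      g1         150          50 183.6436 0.3333333

asymmetry_score(run$profiles[["g1"]], c(48, 51))
#> asymmetry g1 codons [48,51): AS = 0.479 (down 199 / up 416, alpha 0.50)
```

The asymmetry score ≈ 0.48 recovers the planted 50% drop-off (expected AS
= 1 − d = 0.5), and the planted trimer tops the enrichment table. Loop
classification on the bundled synthetic alignment reproduces the two
documented *E. coli* loops:

```r
classify_loops(example_kow_msa(), "EFP_ECOLI")
#>          seq_id      loop loop_len tip label
#> 1     EFP_ECOLI   KPGKGQA        7   K   EFP
#> 2    EFPL_ECOLI SPTARGAAT        9   R  EFPL
#> 3      EFP_RTIP   KPGRGQA        7   R   EFP
#> 4 KOW_LONG_KTIP SPTAKGAAT        9   K OTHER
```

A thin command-line front end covering simulation, preprocessing,
profiling, pause calling and loop classification is installed at
`inst/cli/ribostall`.

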