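# ovIgSeq

Germline immunoglobulin locus annotation and B-cell receptor repertoire
analysis for sheep (and other species with a conventional IGH/IGK/IGL
organisation), with a fully seeded synthetic-repertoire simulator so every
stage can be validated against known ground truth.

## What it does, and for whom

Two audiences, two halves:

* **Comparative immunogeneticists** annotating an immunoglobulin locus on a
  genome assembly: `annotate_locus()` combines template-guided segment
  search with recombination-signal-sequence (RSS) scanning under the 12/23
  rule, classifies each V/D/J segment as functional, ORF or pseudogene
  (simplified IMGT rules), clusters V segments into subgroups at the
  conventional 75% identity cutoff, and writes a germline reference as
  FASTA + GFF3.
* **Repertoire analysts** with rearranged 5'RACE amplicon reads:
  `filter_reads()` applies the length/primer gates,
  `analyze_repertoire()` assigns germline V, (D,) and J genes, decomposes
  each junction into the five diversity factors, extracts CDR3, and judges
  productivity; `mutation_profiles()` and friends quantify somatic
  hypermutation (SHM).

## The models in brief

**RSS.** Heptamer `CACAGTG` and nonamer `ACAAAAACC` separated by a
12 ± 1 or 23 ± 1 bp spacer, with per-motif mismatch budgets (1/2 by
default); V, D and J segments carry the spacer classes the 12/23 rule
dictates for their locus.

**Junction decomposition.** Each read's junction is decomposed as

```
V (− 3'V deletion) | P1 N1 P2 | D remnant | P3 N2 P4 | J (− 5'J deletion)
```

(light chains: a single `P1 N P2` gap). P tracts exist only at undeleted
germline ends and equal the reverse complement of the end read inward
(≤ 4 bp); the D remnant is the placement minimising the untemplated base
count (≥ 5 consecutive matches, else no D); the concatenation of the
parts reproduces the read exactly, by construction. An exhaustive
enumerator (`enumerate_decompositions()`) returns the full equivalence
class of minimal-N decompositions and backs both the simulator's
ambiguity flags and the tests. CDR3 runs between the V 2nd-CYS codon and
the J `[FW]GXG` anchor, anchors excluded; a rearrangement is productive
iff the anchor is in the V frame with no intervening stop — which forces
productive CDR3 lengths to multiples of 3.

**SHM.** `SHM frequency = mutated bases / total aligned bases × 100`;
a 12-type substitution spectrum with transition/transversion aggregation;
per-position maps with FR/CDR labels; and mutation counts of C in `WRCY`
and G in `RGYW` AID hotspot contexts (W = A/T, R = A/G, Y = C/T), with a
hotspot-versus-background per-base rate ratio.

**Simulator.** `simulate_repertoire()` generates reads with usage skew,
truncated-geometric end deletions, P/N inserts, hotspot-biased SHM and
sequencing error — every draw seeded, every choice recorded in a truth
table, and `reconstruct_read()` rebuilds each read byte-for-byte.

## Worked example

```r
library(ovIgSeq)

ref <- make_toy_germline(seed = 7, locus = "IGH")   # 4 V, 4 D, 2 J, 1 C
cfg <- simulation_config(seed = 42, n_reads = 500, shm_rate = 0.02)
sim <- simulate_repertoire(cfg, ref)

fl  <- filter_reads(sim$reads, cfg$fwd_primer, cfg$rev_primer)
fl$report
#>               kept          too_short missing_fwd_primer missing_rev_primer
#>                500                  0                  0                  0

rep <- analyze_repertoire(fl$kept, ref)
usage_frequencies(rep, ref)$j
#>    name count fraction
#> 1 IGHJ1   431    0.862
#> 2 IGHJ2    69    0.138

rt <- recombination_types(rep)
head(rt[, c("v_call", "d_call", "j_call", "count", "fraction")], 3)
#>    v_call d_call j_call count fraction
#> 1 IGHV1S1  IGHD2  IGHJ1   137    0.274
#> 2 IGHV1S3  IGHD2  IGHJ1    62    0.124
#> 3 IGHV1S1  IGHD3  IGHJ1    45    0.090
attr(rt, "n_types")
#> [1] 25

prof <- mutation_profiles(rep, ref)
shm_frequency_of(prof)
#> [1] 2.56
head(substitution_spectrum(prof)[, c("type", "count", "fraction")], 3)
#>   type count  fraction
#> 1  C>T   751 0.1959301
#> 2  G>A   629 0.1641012
#> 3  A>G   434 0.1132272
hotspot_mutations(prof)$rate_ratio
#> [1] 4.92
```

Reading the output: all 500 simulated reads pass the primer/length gates;
J usage recovers the configured skew (0.883/0.117); the dominant
recombination type pairs the dominant V, the (YG)n-motif D and the
dominant J, with 25 distinct types at this depth; the measured SHM
frequency (2.56%) reflects the configured 2% per-base rate lifted by the
five-fold AID-hotspot multiplier, whose recovered rate ratio is 4.92; and
the leading substitution types are the expected transitions.

`run_pipeline(pipeline_config(...))` writes all of the above —
AIRR-style rearrangement TSV, junction/CDR3 histograms, SHM spectrum,
hotspot and position-map CSVs, usage and recombination-type tables, and a
manifest — to an output directory, byte-identically across reruns. A thin
command-line wrapper lives at `inst/scripts/ovigseq.R`
(`annotate | filter | simulate | run`).

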