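---
title: "Models and methods behind ovIgSeq"
author: "ovIgSeq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ovIgSeq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovIgSeq)
```

## Scope

ovIgSeq covers two halves of an immunoglobulin-repertoire study in sheep
(and, by construction, any species with a conventional IGH/IGK/IGL
organisation): **germline annotation** — locating V, D, J and C gene
segments on a genomic sequence and classifying them — and **repertoire
analysis** — interpreting rearranged 5'RACE amplicon reads as V(D)J
recombination products, decomposing their junctions, and quantifying
somatic hypermutation (SHM). A seeded synthetic-repertoire generator with
per-read ground truth makes every stage testable without external data.

## Germline annotation

### Template search

Segments are located by scanning both strands for gap-free occurrences of
each template at or above a minimum identity (`min_identity`, default
0.70, chosen with cross-species templates in mind). The search is
windowed at full template length, so every reported hit covers the whole
template; insertions/deletions between species are not modelled at this
stage. Overlapping hits are resolved by score (+2 per match, -2 per
mismatch), ties by longer alignment, then by lower start coordinate, then
template name — annotation output is therefore byte-reproducible.

### RSS scanning and the 12/23 rule

Recombination signal sequences are found with a plain consensus scan:
heptamer `CACAGTG` (budget 1 mismatch by default), nonamer `ACAAAAACC`
(budget 2), separated by a 12 +- 1 or 23 +- 1 bp spacer. An `N` counts as
a mismatch. The scanner examines every offset on both strands; an
exhaustive per-offset oracle in the test suite confirms equality on
sequences up to 20 kb. Which spacer class flanks which segment type is
locus-dependent (IGH: V-23, D-12/12, J-23; IGK: V-12, J-23; IGL: V-23,
J-12), and the 12/23 rule is implied by that table. RSS motifs are
attached to a located segment when the heptamer lies within `rss_gap`
(default 40 bp) of the coding end in the correct orientation. D and J
candidates can additionally be nominated purely from RSS pairing
(`nominate_by_rss()`) when no template matches.

### Functionality

`classify_functionality()` is a deliberate simplification of the IMGT
decision tree: *pseudogene* when the coding region carries an in-frame
stop codon (or a frameshift relative to the template length, when known);
*functional* when the frame is open, the expected RSS is present within
budgets, and the conserved anchors are found (V: 1st-CYS and 2nd-CYS
codons; J: a `[FW]-G-X-G` motif reachable without a stop); *ORF*
otherwise. Leader exons, promoters and splice sites are not evaluated;
users annotating real loci should treat "functional" as "no defect
detectable at the segment level".

Two counting conventions appear in locus summaries: all template hits,
and RSS-bearing hits only. For D segments only the RSS-paired count is
biologically meaningful (a D without its RSS12 pair cannot recombine, and
short templates produce occasional spurious matches); for V and J the
template-hit count is used.

### Subgroups

V subgroups are single-linkage clusters over pairwise global nucleotide
identity at the conventional 0.75 cutoff: two segments share a subgroup
iff a chain of pairs at >= 0.75 identity connects them. A shared-8-mer
prefilter skips alignments between pairs that cannot reach the threshold,
which keeps the all-pairs pass tractable at a hundred-plus segments.
Cluster labels are ordered by descending cluster size, ties by the first
genomic coordinate. This replaces tree building: a phylogeny is a display
artifact for this purpose, while the thresholded-identity partition is
the quantity the subgroup label actually encodes.

## Read filtering

A read is kept iff it reaches `min_len` (default 400 bp — a complete
rearrangement with primers, leader, V, J and partial C cannot be shorter)
and carries the forward primer near the 5' end and the
reverse-complemented reverse primer near the 3' end (Hamming match,
budget 2, window 60 bp; 5'RACE primers are short and high fidelity, so no
indel tolerance is needed). Rejections are partitioned by the first
failing rule in the order too-short, missing-forward, missing-reverse.
Paired-end assembly is out of scope: input reads are assumed pre-merged.

## V(D)J assignment

Merged amplicon reads are substitution-dominated (SHM and sequencing
error are point events), so alignment is gap-free: each germline segment
is anchored on the read by short seeds (21-mers every 30 bp for V,
allowing 3 mismatches; 12-mers every 6 bp for J, allowing 2), candidate
offsets are evaluated base-by-base, and the best-scoring placement wins
with ties broken score → identity → lexicographic name. Score and
identity come from the maximal-scoring contiguous stretch (+2/-2), i.e. a
gap-free local alignment. Reads without a forward-strand V seed are
retried reverse-complemented. Reads are rejected when the best V identity
falls below 0.70 or the best J identity below 0.80 (J is short, so the
bar is higher), or when the V/J ordering is inconsistent.

The D segment is *not* called during this stage: it is selected during
junction decomposition, where the choice can be made under the same
objective the decomposition itself uses (below). This keeps the reported
decomposition inside the optimal equivalence class by construction.

### Two boundaries, two purposes

A subtlety worth making explicit: the V 3' boundary serves two different
analyses, and using one boundary for both biases one of them.

* For the **junction decomposition**, the retained V must end at the last
  position confidently templated by V. We anchor on the last exact match
  run of at least `min_anchor` (8) bases and extend by exact matches
  only. This is the parsimony boundary: it never attributes a mismatched
  base to V.
* For **mutation tallying**, that same rule would preferentially trim
  mutated positions out of the scored interval (a mutation near the V 3'
  end truncates the run), deflating the SHM rate. Mutation counts and
  their coverage denominator therefore use a different interval: from
  germline position 0 (the amplicons span the complete V, so its 5' end
  is always present) to the gap-free local-alignment 3' end, which steps
  across an isolated substitution when at least two matching bases
  follow. In simulations at 2% SHM this change moved mutation-calling
  recall from 0.944 to 0.996 without material loss of precision.

## Junction decomposition

The junction model is the five-factor decomposition of CDR3 diversity:
3'V exonucleolytic deletion, a P1+N1+P2 insert, the D remnant (heavy
chain), a P3+N2+P4 insert, and 5'J deletion; light chains use the single
V — P1+N+P2 — J gap. Conventions:

* A **P tract** exists only at an undeleted germline end and must equal
  the reverse complement of that end read inward, capped at 4 bp
  (`p_cap`; biological P tracts are short, and observed P lengths in this
  kind of data stay below 5 bp). When a base could be either P or N it is
  assigned to P (greedy, deterministic, matching common reporting
  practice).
* The **D remnant** is the exact common substring (>= `min_d` = 5
  consecutive matches) of a germline D and the V–J gap that minimises the
  total untemplated base count; below the floor no D is called and the
  whole gap is untemplated.
* The concatenation invariant — retained V + P/N inserts + D + retained J
  reproduces the read between the trimmed boundaries — holds for every
  decomposition by construction and is asserted per read in the tests.

`enumerate_decompositions()` is the exhaustive counterpart: it evaluates
every D placement (and the D-less arrangement) and returns all
arrangements achieving the minimal N count. Junctions whose generated
truth is not the unique optimum are flagged *ambiguous* by the simulator
— a generated junction is ambiguous whenever, e.g., an N base happens to
continue the germline V, or a P tract could extend further than drawn.
Under exact parsimony this affects a substantial fraction of junctions
(typically 60–75% at the default insert sizes); it is a property of the
data, not of the algorithm, and the tests require exact truth recovery on
the unambiguous subset and optimal-class membership on the rest.

### Deletion-length bias and its correction

Parsimony boundaries under-report end deletions: whenever the first
untemplated bases coincidentally continue the germline sequence, the
boundary extends through them. With untemplated bases of uniform
composition the coincidental extension is geometric with per-base
probability 1/4, so the measured deletion is `M = max(X - G, 0)` for a
known channel `G`. `estimate_deletion_distribution()` inverts that
channel in closed form,
`P(X = x) = (P(M = x) - q P(M = x + 1)) / (1 - q)`, and reports the
bias-corrected deletion law and mean. In simulations at the default
settings the raw measured mean sits roughly 0.17 bp below the generating
mean; the corrected estimate recovers it to within about 2% at 5000
reads. The raw histograms remain what the per-read junction fields say;
the corrected law is the right quantity for comparing against a
generative model.

### CDR3 and productivity

CDR3 runs strictly between the V 2nd-CYS codon and the J `[FW]GXG`
anchor codon, both anchors excluded. Whether published base-pair lengths
include the anchors is convention-dependent; with anchors included every
length shifts by +6 bp, and the stored junction field (anchors included)
lets either convention be recomputed. A read whose anchors are not
covered, or whose anchor codons no longer encode C / F / W, is excluded
from CDR3 statistics with reason `missing_anchor`. A rearrangement is
productive iff the J anchor codon sits in the V reading frame and no stop
codon occurs from the V start through the anchor — which forces CDR3
lengths of productive reads to be multiples of 3, the 3-bp incrementation
pattern visible in CDR3 length histograms.

## SHM analysis

Only substitutions count as SHM; the scored interval is described above,
and alignment gaps are not modelled (the assignment is gap-free). The
overall frequency is the printed formula: mutated bases / total aligned
bases x 100. The 12-type spectrum is reported as fractions of total
mutations with a transition/transversion aggregate. Per-position maps
carry coverage, counts by type, FR/CDR labels (from the reference's
delimitation; maps are emitted without labels rather than guessed when a
reference lacks them) and the AID hotspot mask.

Hotspots: a germline C at position 3 of `WRCY` and a germline G at
position 2 of `RGYW` (W = A/T, R = A/G, Y = C/T; RGYW is the reverse
complement of WRCY, and the mask obeys that duality exactly). A base
matching both contexts is counted once, with both flags recorded. The
enrichment statistic is the ratio of per-base mutation rates at hotspot
versus non-hotspot positions, using per-position coverage as the
denominator on both sides.

Clonal collapsing (deduplication by identical junction before SHM
tallies) is available behind `collapse_identical_junctions` and defaults
to off, matching frequency reporting without duplicate removal; the exact
collapsing rule used in clonal-selection protocols varies, so the flag is
deliberately blunt.

## The synthetic repertoire generator

`simulate_repertoire()` is the generative inverse of the analysis. Each
read is assembled as

```
[forward primer] leader | V (minus v3 del) | P1 N1 P2 | D remnant |
P3 N2 P4 | J (minus j5 del) | C stub | revcomp(reverse primer)
```

then SHM is applied to the retained V with per-position rates multiplied
at hotspot positions, then uniform sequencing error across the read. One
seed governs every draw in a fixed per-read order, so outputs are
byte-reproducible. The truth table records every generative choice, and
`reconstruct_read()` rebuilds each read from its record byte-for-byte —
the generator's defining invariant.

Defaults are the study conditions the package is tested under, chosen
once from the measured structure of the sheep heavy-chain repertoire and
not revisited:

| parameter | default | rationale |
|---|---|---|
| V/D/J usage (IGH) | 0.581/0.126/0.292/0.001; 0.15/0.55/0.15/0.15; 0.883/0.117 | the strongly skewed usage measured in spleen sample 1: three dominant VH, one dominant (YG)n-motif DH, one dominant JH |
| v3 deletion | truncated geometric, p = 0.35, cap 32 bp | deletions predominantly 0–4 bp, long tail up to the low thirties |
| j5 deletion | p = 0.25, cap 12 bp | observed 0–12 bp range |
| d5/d3 deletion | p = 0.40, cap 10 bp | keeps remnants in the observed 4–17 bp band |
| P tract | probability 0.35 per undeleted end, lengths 1–4 bp (0.55/0.30/0.10/0.05) | P tracts rare and short |
| N length | p = 0.30, cap 34 bp, uniform composition | inserts mostly 0–9 bp with a long observed tail |
| SHM | 2% per base, hotspot multiplier 5 | germinal-centre-experienced spleen repertoire |
| SHM targets | transition-biased per-source weights | makes A→G and G→A the leading types and T→A the rarest, the conserved ordering in this family of data |
| sequencing error | 0.1% per base | merged PE300 reads |
| primers | UPM forward, locus-specific constant-region reverse | the published amplification design |

The toy germline (`make_toy_germline()`, default 4 V / 4 D / 2 J / 1 C
for IGH — the segment counts observed to participate in heavy-chain
rearrangement) builds anchor-correct segments: V with both CYS anchors,
an FR1–FR3/CDR1–CDR2 delimitation and a 10 bp stop-free germline CDR3
tail; J with exactly one `[FW]GXG` motif; D segments including a
(YG)n-motif element (`SYYSGYGYAYGY`); all with correctly oriented RSS
when assembled into a toy genome (`make_toy_locus()`), which can also
plant ORF segments (RSS omitted) and pseudogenes (in-frame stop).

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: insertions/deletions from
sequencing or alignment artefacts, paired-end merging errors, chimeric
amplicons, gene conversion, clonal lineage structure (reads are i.i.d.),
isotype mixtures, and cross-species template divergence patterns beyond
uniform substitution. Conclusions about those failure modes need real
reads.

## Numerical choices and degenerate inputs

* `min_anchor` 8 bp: an 8-mer match occurs by chance once per ~65 kb, so
  anchor runs are effectively never spurious at amplicon scale.
* Maximal-subarray ties resolve to the shortest, left-most interval;
  candidate-offset ties resolve by vote count then evaluation order; all
  remaining ties by name. Identical inputs give identical outputs
  everywhere.
* Overlapping V/J placements are reported as a flagged zero-length
  junction (`negative_gap`), not an error.
* Empty inputs (empty FASTA, empty read set) produce empty outputs with
  zeroed reports; malformed FASTA records abort with the file named.
* Segments on the minus strand are stored reverse-complemented;
  inverted-orientation cassettes are representable, and excluded from
  expressed references by default.

## Problem sizes

The test suite runs the generator at 400–1500 reads per property and the
acceptance checks at 1000 (junction exactness) and 5000 (parameter
recovery) reads; `scripts/acceptance.R` uses 3000-read repertoires and
planted loci of 22/18/128 V segments. These sizes put binomial standard
errors well below the tolerances being asserted while keeping a full run
in the minutes range on one core.

## Known limitations

* Gap-free alignment: a true indel inside V (rare biologically, but
  present in some repertoires) would truncate the scored interval rather
  than be called.
* The functionality rules approximate IMGT; splice and promoter defects
  are invisible.
* Junction ambiguity is intrinsic: exact truth recovery is only defined
  on the unambiguous subset, and boundary-adjacent mutations are
  attributed to N rather than SHM at the parsimony boundary.
* Subgroup labels depend on the 0.75 cutoff; near-threshold pairs can
  re-partition under small reference changes.
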