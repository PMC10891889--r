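---
title: "Methods: annotating and comparing baculovirus genomes"
author: "baculoscribe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and comparing baculovirus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculoscribe)
```

# Scope and model

Baculoviruses carry a single circular double-stranded DNA genome of
80–180 kb that encodes 80–190 densely packed genes on both strands.
Describing a new isolate follows a well-established recipe: predict
and filter ORFs, classify the promoter motifs upstream of each gene,
locate the homologous regions (hrs), compute marker-gene distances for
species demarcation, and compare gene content and order with reference
genomes. `baculoscribe` implements each of those steps as a separate,
individually testable module and adds a seeded simulator that builds
genomes with known truth so the whole pipeline can be validated
end to end.

## Coordinates and the circular topology

All coordinates are 1-based inclusive, the GenBank convention. A
feature with `end < start` spans the map origin of a circular genome;
in GenBank output it becomes `join(start..L,1..end)`, in GFF3 two
`part`-tagged lines sharing an ID. By convention the polyhedrin start
codon defines position 1 of the physical map; `rotateToOrigin()`
re-origins a genome, and the `originNote` slot records which feature
was used. Upstream windows that would wrap more than one full genome
length cannot arise because the window is capped at
`genome length − ORF length`; on linear sequences windows are
truncated with a warning. `N` bases are retained but never match a
motif, never count as a codon and never score as an identity.

# ORF annotation

`findOrfs()` scans six frames. Internally the circular genome is
tripled and only ATGs whose position falls in the middle copy are
reported — that gives every start a full upstream context (so the
"most upstream ATG after the previous in-frame stop" rule is evaluated
correctly across the origin) while guaranteeing each ORF is reported
exactly once. The per-frame scan is byte-coded and vectorized, so a
full 160 kb genome takes a fraction of a second.

Decisions a user should know about:

* An ORF is the **longest** open frame: first ATG after the previous
  in-frame stop, through the first stop. The literature is not
  explicit about which variant different gene finders agree on, so the
  shortest-ATG variant is available via `variant = "shortest"`.
* `minAa = 50` (amino acids, excluding the stop) is the conventional
  annotation floor.
* `resolveOverlaps()` measures overlap on plus-strand projected
  circular intervals; pairs overlapping more than 75 bp lose the
  smaller member unless it is flagged as a conserved homolog. When the
  two ORFs are equally long, the plus-strand one, then the one with
  the lower start, is kept — a tie-break the convention leaves
  unstated, fixed here for determinism. The operation is idempotent.
* `maskHrOrfs()` removes ORFs lying **entirely** inside an hr locus
  (they are considered unstable); partial overlaps survive. The
  pipeline therefore detects hrs before emitting the final ORF table.
* `genomeStats()` computes G+C on unambiguous bases only and the
  coding fraction on the union of ORF spans (overlaps counted once —
  the alternative, counting them twice, is not a genome fraction).
* Locus tags are assigned in ascending start order from the rotated
  origin, the naming scheme used on baculovirus physical maps.

# Promoter classification

The 180-nt window 5′ of each start codon is scanned on the coding
strand only; antisense promoter elements are not considered. Offsets
are signed, with −1 the base immediately 5′ of the A of ATG. Early
evidence is a `TATAW` motif with a `CAKT` motif 25–35 nt downstream —
measured start-to-start, boundaries inclusive, another convention fixed
here because anchor points are usually left implicit — or a `TAATWAA`
element, which counts as early evidence on its own. Late evidence is
any `DTAAG`. Classes are `early`, `late`, `both`, `none` and always
partition the input.

For summary statistics one representative motif per ORF enters the
averages: the TATA/CAKT pair whose TATA sits closest to the start
codon, and the DTAAG closest to the start codon. Published census
averages report one value per gene without naming the representative;
nearest-to-start is the natural choice for elements that position the
transcription start.

`promoterSummary()` accepts any subset of loci because published
censuses are often restricted (e.g. to the genes unique to an
isolate); `scanPromoters(loci = ...)` mirrors that.

# Homologous regions

An hr is modelled as ≥ 2 adjacent tandem copies of a 50–250 bp unit
(the band brackets the ~112 bp units typical of group II
alphabaculoviruses) whose consensus contains an imperfect palindrome
centered in the unit.

`findTandemRepeats()` re-implements tandem-array detection rather than
wrapping an external finder, using a transparent two-stage design:

1. **Period estimation.** Exact 12-mers are packed into 24-bit
   integers (no hash collisions); every re-occurrence of a 12-mer at a
   distance inside the period band casts a vote `(position, distance)`.
   Clusters need at least 6 concordant votes: a random 10 kb sequence
   produces ~0.1 votes in total, so the null yields no arrays (the
   test suite asserts this over 20 fixed-seed replicates), while even
   a 2-copy array at 10% unit divergence produces dozens.
2. **Phase refinement.** Every offset of the unit frame over the
   candidate region is decomposed into consecutive units and segmented
   by the identity of *adjacent* unit pairs; the longest concordant
   run wins, scored by run length then total pair identity. Adjacent
   pairs (not a region-wide consensus) are compared because background
   units inside the search window would otherwise contaminate the
   consensus and depress true-unit identities. The winning run's
   majority-vote consensus (ties to the alphabetically first base)
   defines the reported units and identities.

On substitution-diverged synthetic arrays this recovers the planted
period exactly and boundaries within ±2 bp (phase ties between
rotations of the unit frame can shift boundaries by a base or two; for
a tandem array all rotations are equally valid decompositions).

`findPalindromes()` reports, for every center and loop gap up to
`maxGap`, the maximal arm such that at most `maxMismatch` arm pairs
fail to complement; defaults (`minArm` 10, `maxGap` 8, `maxMismatch`
3) admit the ~26 bp imperfect cores reported for alphabaculovirus hrs
and are all tunable since published analyses rarely state the
parameters of the palindrome searches they ran. Because arms extend as
far as the budget allows, a planted 26 bp core is often reported with
a slightly wider maximal span; tests therefore assert span ≥ planted.
The output is strand-symmetric (invariant under reverse complement).

`assembleHrs()` accepts an array iff its consensus contains a
palindrome whose center lies in the central third of the unit, names
loci `hr1…` in genome order, and records A+T richness without
filtering on it — AT-richness is a described property of hrs, not a
defining criterion.

# K2P distances and demarcation

`globalAlignPair()` produces an end-to-end affine-gap alignment
(match +5, mismatch −4, gap of length *k* costs 10 + 0.5 *k*) through
`Biostrings::pairwiseAlignment()`; a multiple-alignment program is
deliberately not required, since for a single pair the optimal global
alignment is exact and dependency-free. Alignment parameters are
recorded on the returned object because distances inherit them.
Biostrings' tie-breaking between co-optimal alignments is
deterministic, which is what reproducibility needs.

`k2pDistance()` excludes columns with a gap or N in either sequence
(pairwise deletion — gaps are missing data), computes transition and
transversion proportions P and Q over the remaining n sites and
returns `d = −½ ln[(1 − 2P − Q) √(1 − 2Q)]`, assuming uniform rates
across sites. `defined = FALSE` flags saturation
(`1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0`); n = 0 is an error. When the
substitution classes are balanced (P = p/3, Q = 2p/3) the formula
reduces exactly to the Jukes–Cantor distance, which the tests verify
to 1e−9, and the implementation is cross-checked against
`ape::dist.dna(model = "K80")`.

`demarcateSpecies()` applies the baculovirus rule: **novel** iff every
supplied marker distance exceeds 0.05 substitutions/site,
**not_novel** iff all are at or below it, otherwise (mixed, or any
saturated marker) **inconclusive**. Finer same-species bounds exist in
the literature but are not asserted; the threshold is a parameter.

# Comparative module

All-vs-all exact Smith–Waterman under BLOSUM62 (gap open 11, extend 1)
replaces heuristic database search: a baculovirus proteome holds only
~150 proteins, so exhaustive optimal alignment is tractable and
removes E-value and database-size dependence. A homolog pair is a
reciprocal best hit with score ≥ 70 and identity ≥ 25%. The score
floor was calibrated once on the simulator's shuffled-decoy null
(maximum null best-hit scores across replicates fall in the 50s–60s
for 15-protein proteomes of 120–400 aa), so decoy proteomes yield zero
pairs; the identity floor is the usual twilight-zone guard.

`parityPoints()` turns homolog pairs into ordinal gene-rank
coordinates — the gene parity plot — and summarizes collinearity as
the Spearman rank correlation, which is exactly 1 for self-comparison
and −1 for a reversed gene order. Gene order is ascending start
coordinate from the rotated polyhedrin origin, which is why parity
plots of closely related genomes can show an apparent inversion
through the origin: it is an artifact of defining polyhedrin as ORF1.

`wholeGenomeIdentity()` aligns two plus strands end-to-end in linear
space with a divide-and-conquer affine aligner (Rcpp; match +5,
mismatch −4, gap open 16, extend 4, end gaps penalized) and reports
identical columns over alignment length. The linear-space recursion is
verified against a quadratic-space full-matrix oracle on fuzzed
instances. The comparison is run once, plus strand versus plus strand,
after both genomes are rotated to a common origin; no reverse-strand
trial is attempted. Runtime is O(n·m), so full-length 100+ kb genome
pairs take hours on one CPU; the examples and the acceptance script
use 20 kb fragments, which preserve the statistic's behaviour.

`concatenateCoreAlignments()` produces the core-gene supermatrix and a
partition table for external tree software; tree inference itself
(model selection, ML search, bootstrap) is out of scope by design.

# The synthetic-data generator

`makeGenome()` turns a `GenomeSpec` into a genome plus a truth table.
Design choices, and what they mean for interpreting green tests:

* **Background is i.i.d.** at the requested G+C (default 45%, the
  alphabaculovirus neighbourhood). That is enough to give motif scans
  and repeat finders a realistic null, but real genomes have
  dinucleotide structure, skews and repeated gene families that the
  simulator does not emulate — recovery rates on synthetic genomes
  validate the algorithms' correctness, not their performance on real
  data.
* **ORF cassettes** are `TAA | ATG | sense codons | stop`. The leading
  in-frame stop pins the most-upstream-ATG rule to the planted start,
  making coordinate truth exact.
* **Promoter-bearing ORFs** get a ≥ 200 bp clear upstream zone so the
  180-nt window lies in background sequence; planted motifs are
  written at recorded offsets (TATA at −90…−50, spacing 25–35, DTAAG
  at −80…−40) and the window is scrubbed of any other class-changing
  motif. Densely packed ORFs without a promoter class carry no
  promoter truth — their windows overlap neighbouring genes, as in
  real genomes, where published censuses also restrict themselves to
  selected loci (the default study-shaped census is 17 loci: 3 early,
  8 late, 2 both, 4 none).
* **hr cassettes** are tandem units (default 112 bp, AT-rich) with a
  centered palindrome of planted span and mismatch count; per-unit
  divergence (default 3%) is applied outside the palindrome so the
  core's mismatch count stays exactly as planted.
* **A scrub loop** removes spurious ORFs so planted precision and
  recall are exact: spurious ORFs in free background receive an
  in-frame stop; spurious frames inside a planted host ORF are
  destroyed by swapping one interior host codon for a sense codon that
  reads as a stop in the spurious frame (the host's protein changes,
  its coordinates and validity do not). ORFs wholly inside hrs are
  left for `maskHrOrfs()` to remove, as in the real pipeline.
* **Determinism.** Three seeded streams (layout, sequence,
  mutation/scrub) derive from the spec seed; the same spec and seed
  give byte-identical genomes, and adding a feature category does not
  shift the other streams.

`evolveSequence()` simulates the K80 process site-independently using
the exact transition probabilities at the requested divergence, with
κ = `tsTvRatio` (α/β); the expected K2P estimate of an input/output
pair equals the requested distance, making it the calibration
instrument for the distance module. `makeOrthologPair()` mutates
random proteins to a target identity and appends decoys, providing the
RBH truth and null.

# Problem sizes and numerical choices

The test suite validates truth recovery on a 62 kb, 50-ORF
study-shaped genome and the acceptance script on the full 160 kb,
140-ORF configuration; both carry the complete architecture (17-locus
promoter census, hrs of 4/3/2 × 112 bp units), and the smaller size
keeps the default test run fast. Estimator recovery uses 10 kb
sequences and 50 replicates per divergence (0.05, 0.1, 0.3
substitutions/site), asserting the mean within three standard errors.
Oracle-equivalence checks (motif scan, palindromes, global and local
alignment) run on fuzzed instances up to a few hundred bases, where
exhaustive brute-force references are cheap.

Known limitations: hr detection is linear (an hr spanning the map
origin of a circular genome would need a prior rotation); the
generator plants substitution divergence only (no indels inside
repeat units, no gene duplications); promoter truth is only defined
for loci with clear upstream windows; and whole-genome identity at
full genome scale is compute-bound by design, being an exact
alignment.
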