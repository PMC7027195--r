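---
title: "Detecting systematic nucleotide-exchange (swinger) RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting systematic nucleotide-exchange (swinger) RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swingerseq)
```

## The problem

Expressed sequence tags (ESTs) and other short reads (100–600 nt) are
routinely discarded when they show no homology to their template genome.
A subset of such "unknown" reads are *swinger RNAs*: transcripts in which
the polymerase systematically exchanged nucleotides, for example writing
T wherever the template dictated A and vice versa. Because only 23
non-identity bijections of {A, C, G, T} exist, the template of such a
read can be found by exhaustive search: apply each of the 23 exchanges to
the read and re-run homology search. Random sequencing artefacts cannot
mimic a systematic exchange, which is what makes a transformed-alphabet
hit informative.

`swingerseq` implements this search and the downstream analyses: where on
a gene the swinger hits fall (5′/mid/3′ compartmentalization, exon/intron
structure), how class abundance relates to alignment length, and how
amino-acid conservation of an exchange relates to its abundance.

## The transformation algebra

The 23 exchanges split into 9 *symmetric* involutions (6 single swaps
such as A↔T and 3 double swaps such as A↔T+C↔G) and 14 *asymmetric*
directional cycles (8 three-cycles, 6 four-cycles). They form, together
with the identity, the symmetric group on the four bases, which the
package exploits in two places:

* **Inversion.** A read detected by applying exchange *t* was transcribed
  from its template by the inverse exchange *t⁻¹*. For symmetric
  exchanges the two coincide; for cycles they differ (A→T→C→G→A inverts
  to A→G→C→T→A), and the package reports both
  (`detection_transformation`, `transcription_transformation`).
* **Strand canonicalization.** With the complement map *c* = A↔T+C↔G,
  `rc(t(s)) = (c∘t∘c)(rc(s))` for every sequence *s*. A hit found by
  aligning the transformed read against the reverse strand is therefore
  re-expressed on the forward strand through the conjugate `c∘t∘c` and
  reported with `strand = "-"`. The exhaustive 24×24 composition table
  and this conjugation identity are verified in the test suite.

Canonical names follow the field's notation (A↔T, A→T→C→G→A); ASCII
aliases (`"A<>T"`, `"A-T-C-G-A"`) are accepted everywhere because arrow
glyphs travel poorly through file formats.

IUPAC ambiguity codes are mapped set-wise: the image of a code is the
code whose base set is the image of its base set, so transformation
commutes with ambiguity semantics and N is always fixed. How the original
screen treated ambiguity codes is not documented; this rule is the
package's own choice.

## Detection

`detect_swinger()` aligns the untransformed read and its 23 transformed
variants, each in both orientations, against every reference sequence
with an affine-gap Smith–Waterman aligner (match +2, mismatch −3, gap
open −5, gap extend −2 — classic blastn-like scores; the original screen
used megablast, whose scoring is not part of the method's logic). For
long references the best-scoring cell is located with a linear-memory
scan and the traceback is recomputed on a window that provably contains
the optimal local alignment. Thresholds default to 40 nt minimum aligned
length and 75% minimum identity, bracketing the extremes of the published
validated hits (41 bp; 75.404%).

Design choices that were genuinely open:

* **Canonical-first short-circuit.** Canonical reads dominate real
  libraries, so the identity alignment is tried first. A canonical
  alignment short-circuits the swinger scan only when it is *decisive*:
  it must pass the thresholds **and** cover at least half the read
  (`min_canonical_coverage = 0.5`). On a 100 kb random reference a
  ~40-column, ~76%-identity self-alignment arises by chance for a few
  percent of reads; under a naive short-circuit such a spurious match
  would mask a near-perfect swinger explanation. Weak canonical
  candidates instead compete by score in the exhaustive stage, where the
  identity explanation is still preferred on ties.
* **Tie-breaking.** Among equal-scoring candidates the order is: fewer
  moved bases in the transformation, canonical name (byte order),
  reference order, smaller reference start, smaller query start, shorter
  alignment. Ties between *different* transformations at the best score
  set `ambiguous = TRUE`. The scan itself resolves equal cells toward
  the smallest reference end, then query end, making output fully
  deterministic.
* **E-values are not computed.** Calibrating Karlin–Altschul statistics
  for a custom aligner would not match any published numbers; the
  packaged tables carry printed e-values as text only.
* **Paper-scale runs.** The dynamic-programming scan is exact but
  deliberately unindexed; genome-scale screens should import external
  tabular hits (`import_tabular_hits()`, BLAST outfmt-6 plus a
  transformation column) produced by any aligner.

## Annotation

Genes are split into three equal regions (5′, mid, 3′). A hit belongs to
the region containing its midpoint `floor((start+end)/2)`, computed after
flipping coordinates to the gene's 5′→3′ direction; positions exactly on
a boundary (`floor(L/3)`, `floor(2L/3)`) belong to the earlier region.
The midpoint rule is the package's choice — counting by majority overlap
or fractionally would also have been defensible, but the midpoint is
deterministic, integer-valued, and insensitive to small threshold
effects. Thirds use the transcript length when the reference is a
transcript and the genomic span otherwise.

`classify_structure()` is exhaustive per (hit, model) pair: `exonic`,
`intronic`, `spanning` (overlapping both), or `intergenic`. Gene models
load from BED12 (0-based half-open, converted on read).

## Statistics

* **Sign tests.** The thirds analysis uses an exact one-tailed binomial
  upper tail with null probability 2/3 (the chance of landing in mid∪3′
  at random), summed in log space; no normal approximation. With the
  published counts: P(38 of 43) = 1.06×10⁻³ and
  P(33 of 33) = (2/3)³³ = 1.545×10⁻⁶. The second value is sometimes
  quoted as 1.6×10⁻⁶, which is what one obtains from a rounded null of
  0.667; the package reports the exact value.
* **Abundance–length correlation.** Pearson correlation of log₁₀
  abundance against mean aligned length over the detected classes, with
  the p-value from the t transform on n−2 degrees of freedom. The log
  scale is the default because class abundances span orders of
  magnitude (219 vs 1) and because it reproduces the published
  r = 0.96 / P = 0.00945 (raw abundances give r ≈ 0.906); a raw-scale
  option exists.
* **Conservation index.** For each exchange, the fraction of the 64
  codons whose translation under the standard genetic code (stop as a
  21st class) is unchanged when the exchange is applied to the codon.
  This is the simplest defensible definition — unweighted by codon usage
  and exposed as a pluggable `code` argument — and it is *not*
  guaranteed to equal the metric used in earlier swinger work, which is
  defined in other publications. With the published 23-class abundance
  vector it yields a positive correlation (r ≈ 0.25, below the published
  r = 0.4187); only the direction is treated as reproducible.

## The synthetic-data generator

`simulation_config()` defaults describe the regime the detector targets:
one 100 kb i.i.d. reference at GC 0.41 (human-like), reads of 100–600 nt
(the EST length range), the `"paper-like"` class skew (63% A↔T,
36% A→T→C→G→A, the remaining three detected classes thinly), equal
strand orientation, and substitution-only noise — hits are characterized
by length and %identity, so indels are off by default (an option exists
for aligner stress tests). Reads are planted by cutting a fragment,
optionally reverse-complementing it (the template is then the minus
strand), applying the drawn exchange, and noising; the truth table makes
every read exactly reconstructable, which the tests verify.

What the generator does *not* emulate: repeat structure and
low-complexity tracts of real genomes (which create mapping ambiguity),
expression-level clustering of reads on hot genes, chimeric
canonical/swinger reads, and sequencing-quality artefacts. Passing the
planted-read tests therefore demonstrates correctness of the search over
the transformation space, not performance on real repetitive genomes.

## Problem sizes and numerical notes

The packaged checks run the detector on a 100 kb reference with 25
zero-noise planted reads (recovery and locus accuracy are both 100% under
the shipped seeds), verify detector choices against an exhaustive
(transformation × orientation × offset) oracle on ≤200 nt references,
and track mean percent identity against 100×(1−noise) at noise rates 0,
0.02 and 0.05 on 5 kb references; these sizes keep the full suite within
a few minutes while exercising every code path. Alignment scores are
integers throughout; the sign-test summation is exact to double
precision (checked against the binomial tail for all k, n ≤ 60);
correlation p-values agree with `cor.test` to 10⁻⁹.

## Known limitations

* The exact-DP scan is quadratic; genome-scale screens go through the
  external-hit import path by design.
* Chimeric reads (part canonical, part swinger) are not segmented.
* The conservation metric reproduces the direction, not the magnitude,
  of the published conservation–abundance correlation (see above).
* Published coordinates carried in the fixtures reflect the printed
  tables verbatim, including one internal inconsistency of the source
  (the single G↔T record prints 147 bp / 93.197% where the source's
  prose says 152 bp / 89.47%); the prose vector is used where a printed
  statistic is being reproduced.
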