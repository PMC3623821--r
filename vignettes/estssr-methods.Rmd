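---
title: "Methods: EST-SSR marker development with estssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EST-SSR marker development with estssr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estssr)
```

## Overview

`estssr` implements the complete desk-side workflow for developing simple
sequence repeat (SSR, microsatellite) markers from expressed sequence tags
(ESTs): cleaning a raw transcript set, detecting perfect and compound
microsatellites, designing flanking PCR primers, projecting loci onto a
reference genome and classifying them into gene regions, scoring marker
diversity from genotype tables, summarising cross-species transferability
as a bootstrap-supported neighbor-joining tree, and testing GO-term
overrepresentation among SSR-containing sequences. A family of seeded
generators produces every input format with known ground truth, so each
stage is testable end to end at desk scale.

This vignette records the models, the parameters that matter, and the
design decisions taken where the workflow admitted genuinely open choices.

## Sequence preprocessing

Raw EST sets carry terminal poly-A/T stretches, very short fragments,
vector/organelle contamination and heavy redundancy. The cleanup stage is:

1. **Poly-A/T trimming.** Maximal terminal runs of A or T (either base at
   either end, because EST orientation is unknown) of at least
   `trim_run_min = 10` exact bases are removed, iterating until no
   terminal run qualifies. Iteration makes the operation idempotent;
   interior runs are never touched. Ten bases is long enough that chance
   terminal runs in random sequence are rare (p ≈ 4^-10 per end per base)
   while true poly-A tails are comfortably longer.
2. **Length filter.** Sequences shorter than `min_length = 100` bp after
   trimming are dropped ("shorter than" is strict: a 100 bp sequence is
   kept). Shorter fragments cannot host an SSR plus two 50 bp primer
   flanks.
3. **Contaminant screen.** A record is removed when its best local
   alignment against any contaminant reference (scored match +1,
   mismatch −1, gap −2) reaches 90% identity *over the aligned columns*
   while covering at least 50% of the record. A shared exact 12-mer is
   required before any alignment is attempted; this prefilter cannot
   discard a qualifying hit, because a gap-free stretch of ≥ 12 matching
   bases is implied by the identity/coverage thresholds at these lengths.
   Classes are charged in the fixed order vector → chloroplast →
   mitochondrial so that accounting is single-charge and reproducible.
   The identity denominator (aligned columns) and the thresholds are
   documented choices: published EST pipelines name the screening tool but
   not its parameters, so these numbers define *this* package's screen
   rather than reproducing any particular study's.
4. **Redundancy clustering.** Greedy incremental clustering in the style
   of CD-HIT: sequences are visited longest first (ties by id); each joins
   the first representative with identity ≥ 90%, where identity is
   matches in the best local alignment divided by the length of the
   *shorter* sequence — the cited tool's documented convention — else it
   founds a new cluster. An 8-mer shared-word prefilter keeps the
   comparison count down. Greedy longest-first clustering is
   order-deterministic, which the tests exploit.

Every run produces an accounting report with the invariant
`n_input = n_valid + removals`, checked at construction.

N and IUPAC ambiguity codes never count as matches anywhere in the
package: not in screening, not in clustering identity, not in repeat runs.

## SSR detection

A perfect SSR is a maximal tandem run of a *primitive* motif (one that is
not a whole-number power of a shorter word) of period 2–6. Mononucleotide
runs are deliberately excluded. Three criteria presets are built in:

| preset | thresholds | note |
|---|---|---|
| `misa_default` | di ≥ 10, tri ≥ 6, tetra ≥ 5, penta ≥ 4, hexa ≥ 3 repeats | the package default |
| `cardle` | di ≥ 7, tri ≥ 5, tetra ≥ 4, penta ≥ 3 | hexanucleotides are not searched: only four thresholds define this preset, and we document the omission rather than invent a fifth |
| `len20` | any period 2–6, ≥ 2 repeats, total length strictly > 20 bp | an approximation to length-threshold searches whose exact internals are not published |

Detection slides a period-p shift comparison over the sequence
(`s[i] == s[i+p]`), finds maximal true-runs, and reports each run whose
full-copy count meets the preset threshold. Key conventions:

* Coordinates are 1-based inclusive externally (internal arithmetic is
  0-based half-open); a locus spans exactly `repeat_count × period` bases.
* Trailing partial copies are ignored entirely: counts are floors, and the
  locus end excludes partial copies ("perfect SSR" semantics). One
  consequence, surfaced by the strand-symmetry property test: when partial
  copies flank a run, the whole-copy interval is anchored at the leftmost
  base, so the reported interval on the reverse strand can shift by up to
  period − 1 bases, while class, count and the underlying run mirror
  exactly.
* Primitivity filtering prevents an (AT)n run from being re-reported as
  (ATAT)m; if runs of different periods still occupy the *identical*
  interval, only the shorter-period description is kept.
* Motifs are grouped into canonical classes invariant to phase and strand:
  the class of motif M is "m/m′" where m is the lexicographic minimum over
  all cyclic rotations of M and of its reverse complement. The numbers of
  classes per period are 4, 10, 33, 102 and 350 — verified in the tests by
  exhaustive enumeration.

Consecutive loci on a sequence separated by at most `max_interruption =
100` bp are chained into compound SSRs (chains may exceed two members);
the count conservation `|singletons| + Σ members = |loci|` is asserted in
the tests. Summaries report counts and shares by period and class, mean
repeat count, single- versus multi-SSR sequence counts, density (kb of
searched sequence per locus — undefined, not an error, at zero loci) and
the SSR-containing-sequence frequency.

The detector is validated against a brute-force oracle that tests every
(start, period) pair by direct substring comparison, on a thousand seeded
random sequences per run, for all three presets.

## Primer design

Published marker studies typically delegate primer design to an external
tool with unstated parameters. `estssr` instead ships a transparent
exhaustive enumerator whose behaviour *is* its contract: every candidate
window obeying the constraints is scored, so an independent
re-enumeration must find the same optimum (and does, in the tests).

Defaults: primer length 18–27 nt (optimum 20), melting temperature
57–63 °C (optimum 60), GC 30–70% (optimum 50), product 100–300 bp,
minimum flank 50 bp. Two Tm models are provided: the Wallace rule
2(A+T) + 4(G+C) and, by default, nearest-neighbor thermodynamics with the
SantaLucia (1998) unified parameter set, entropic salt correction
0.368·(N−1)·ln[Na⁺], 50 nM oligo and 50 mM Na⁺. Primers containing a
self-complementary word of ≥ 8 bases are rejected — a deliberately simple
hairpin/dimer guard; full thermodynamic folding is out of scope.

A pair's penalty is the sum over both primers of weighted deviations from
the length/Tm/GC optima (weights 1 per base, 1 per °C, 0.2 per GC point)
plus 1 per °C of pair-Tm difference. The three best pairs per locus are
kept, with deterministic tie-breaks (smaller product, then leftmost
forward start). Widening any constraint range can only enlarge the
candidate set, so the best penalty is monotone — asserted as a property
test. The M13(−21) tail `TGTAAAACGACGGCCAGT` can be prefixed to the
forward primer for universal fluorescent genotyping; tailing twice is an
error.

## Genome placement and region classification

Loci are placed via precomputed 12-column tabular alignment hits (the
aligner itself is out of scope). Hits at identity ≤ 0.8 are discarded —
the cut is strict and on the fraction scale. Among survivors the best hit
per query has the highest bitscore, ties broken by longer alignment, then
lexicographic subject, then smaller subject start; the tie-break is a
documented choice since published pipelines rarely state one.

A locus fully inside the hit's query interval is projected by affine
offset (`g = subject_start ± (q − query_start)`; a subject interval with
start > end encodes the minus strand); a locus sticking out is unplaced
rather than partially mapped. With `refine = TRUE` and the segment
sequences available, a global pairwise alignment (match +1, mismatch −1,
gap −2) of the hit's query segment to its subject segment supplies the
position map instead, absorbing indels — this built-in refiner replaces
the external-realigner step of typical pipelines without invoking any
binary.

Classification against GFF3 gene models: the placement is attributed to
the gene with the largest summed feature overlap, then to the feature
class (CDS / 5′UTR / 3′UTR) with the largest base overlap, ties resolved
CDS > UTR5 > UTR3; zero overlap is intergenic; a chromosome absent from
the annotation yields "unplaced" with a warning. Classification is total:
every placement receives exactly one class.

## Marker diversity statistics

From a genotype table (unordered diploid allele pairs, missing allowed,
pairwise per-locus deletion — the convention of standard population-
genetics spreadsheets), the package computes per locus: the number of
distinct alleles N_A, allele frequencies P_i (allele counts over twice
the typed individuals), expected heterozygosity H_E = 1 − ΣP_i², its
small-sample variant uH_E = 2n/(2n−1)·H_E, and the polymorphism
information content. Two PIC formulas are provided because the field uses
the same name for both:

* `printed` (default): PIC = 1 − ΣP_i², which is *identically* H_E — the
  package asserts this identity in its tests. Marker studies often print
  this formula even when their PIC and H_E columns differ, which implies
  a different calculator was actually used; keeping both forms makes the
  ambiguity explicit instead of resolving it silently.
* `botstein`: 1 − ΣP_i² − Σ_{i<j} 2P_i²P_j², the form implemented by the
  commonly cited PIC calculator; always ≤ the printed form.

A locus is polymorphic iff N_A ≥ 2 among typed individuals; rates are
reported to one decimal percent. The effect of repeat count on
polymorphism is fitted as a maximum-likelihood logistic regression
(IRLS via `stats::glm`, ≤ 25 iterations, tolerance 1e−8) with Wald
tests, reported alongside the point-biserial Pearson correlation — both
are labelled, because "correlation coefficient from a logistic model" is
ambiguous in the marker literature. Complete separation is detected
(zero residual deviance or runaway estimates) and flagged instead of
reporting a meaningless finite slope. The tests check the fit against
direct likelihood maximisation (`optim`) to 1e−4 and against the
closed-form log odds ratio on grouped data.

## Transferability and the NJ tree

Cross-species amplification is scored 1/0 per (species, locus) with
missing cells allowed. No distance is canonical for such data, so the
package uses the simple mismatch proportion with pairwise deletion of
missing cells (the p-distance on binary characters) — the closest match
to how standard phylogenetics software treats binary data; a species pair
with no jointly scored locus is an error, not a silent zero.

Neighbor joining follows Saitou–Nei with the standard Q criterion and two
documented determinism rules: ties in Q are broken by the
lexicographically smallest pair of subtree keys (a subtree's key is its
smallest leaf label), and a negative branch-length estimate is clamped to
zero with the deficit transferred to its sibling so the joined-pair
distance is preserved. At the final three-taxon star the closed-form
lengths are clamped at zero without a transfer (with two siblings the
transfer target would be arbitrary). On exactly additive distances the
algorithm provably recovers the generating topology and branch lengths;
the tests verify this on 100 random trees of 4–8 taxa and cross-check the
topology against `ape::nj`.

Bootstrap support resamples loci (columns) with replacement, rebuilds
distance and tree, and reports for each internal edge of the full-data
tree the percentage of replicate trees containing the same bipartition
(canonicalised by the side not containing the first label). 1000
replicates by default; the seed is mandatory. Replicates whose resample
leaves a species pair with no shared scored locus are skipped, up to a
tolerance of 10% of the replicates.

## GO enrichment

For each term present in the background map, a 2×2 table (subset × term)
is tested with Fisher's exact test, one-sided for overrepresentation by
default (the stated question), with the two-sided variant selectable. The
hypergeometric tail is computed in log space (`lchoose` + log-sum-exp),
overflow-safe for margins to 10⁶, and verified against exhaustive
enumeration to 1e−10 for margins ≤ 30. Benjamini–Hochberg q-values use
the step-up construction (via `stats::p.adjust`, verified against the
direct formula), applied globally across namespaces — whether published
analyses adjust per-namespace is usually unstated; global adjustment is
the conservative single choice. The enrichment fold is the term's
relative frequency in the subset over its frequency in the whole
background. The input map is taken as given: no GO-graph ancestor
propagation is performed, which matters when comparing against annotation
tools that propagate.

## Synthetic fixtures

Every generator is a pure function of its arguments and seed, emitting
exactly the formats the pipeline reads, plus ground truth:

* **EST sets** — backgrounds are rejection-sampled until the detector
  finds no SSR, then planted runs are inserted and the sequence is
  re-screened until detection returns exactly the planted locus set.
  Recall and precision of the detector on fixtures are therefore exact
  quantities, not approximations. Duplicates are verbatim copies under
  new ids; contaminant records are substrings of the synthetic
  vector/chloroplast/mitochondrial references. Defaults (30 sequences of
  300–800 bp, one planted SSR per period) are sized so the whole suite
  runs in minutes on one CPU.
* **Genotypes** — diploid draws from specified allele frequencies under
  random mating, with a missing-data rate.
* **Transferability matrices** — each edge of a generating topology gets
  a dedicated block of characters flipped across exactly that edge, so at
  zero added noise the pairwise mismatch distances are *exactly* additive
  on the tree and NJ must recover it with saturated bootstrap support.
  (An all-zero per-edge flip probability would make every row identical
  and the tree unidentifiable; the block construction is the identifiable
  realisation of "zero noise".) An optional per-cell flip rate then
  degrades the signal smoothly.
* **Annotation maps** — independent per-term Bernoulli annotation, with
  the planted terms' subset rate solved so the *measured* enrichment fold
  (subset frequency over whole-background frequency, the statistic
  `enrich()` reports) has the requested expectation.
* **Genome fixtures** — a toy chromosome with tiled genes whose
  UTR5/CDS/UTR3 layout is known, ESTs cut as exact substrings, and exact
  alignment hits; true placements and region classes follow by
  construction, on either strand.

What the fixtures deliberately do not emulate: sequencing error,
expression-level effects, isoforms, real codon structure, GC bias, or
linkage between loci. Passing tests therefore demonstrate correctness of
the algorithms under their stated models, not robustness to every
artefact of real transcriptome data.

## Problem sizes and numerical choices

The shipped test-suite sizes — 1000 random sequences of ≤ 1.2 kb for the
detector-oracle equivalence, 100 random trees of 4–8 taxa, 300 random
2×2 tables, 500 individuals for frequency recovery, 1000 bootstrap
replicates on 8 species — are the package's chosen verification scale:
large enough that every code path and tie-break is exercised, small
enough to run interactively. Floating-point comparisons use explicit
tolerances (1e−10 for Fisher vs enumeration, 1e−8 for tree length
recovery, 1e−4 for IRLS vs direct maximisation); allele-frequency
recovery is judged at three binomial standard errors; and all stochastic
checks are seeded.

## Known limitations

* Imperfect (mismatch-tolerant) SSRs and mononucleotide runs are not
  detected.
* The contaminant screen and clustering use heuristic k-mer prefilters;
  pathological low-complexity references could in principle evade the
  12-mer prefilter only by having no 12 consecutive matching bases, which
  the identity/coverage thresholds already exclude.
* Primer enumeration is exhaustive within its search windows, whose reach
  is bounded by the maximum product size; the candidate cross product can
  grow into the millions on GC-balanced flanks, which is memory-bound
  rather than slow.
* Amplification success is not predicted; the amplification-rate
  reporting consumes observed validation counts.
* The pipeline assumes non-overlapping loci when merging compounds, which
  the detector guarantees per period but exotic cross-period overlaps
  would surface as the documented upstream error.
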