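---
title: "Methods: breakpoint discovery from long-insert mate pairs"
author: "svbreaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breakpoint discovery from long-insert mate pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svbreaks)
```

## The problem

Long-insert mate-pair libraries sequence the two ends of ~4-6 kb DNA
fragments. After mapping, the distance and relative orientation of the two
reads estimate the fragment's span on the reference. A structural variant
-- a deletion, insertion, inversion, or translocation -- breaks that
expectation for every fragment straddling its junction: the reads land too
far apart, too close, in the wrong orientation, or on different
chromosomes. `svbreaks` detects breakpoints by modelling what a concordant
pair looks like, collecting the discordant ones, and clustering them into
junction calls; it then supports downstream triage (germline vs somatic),
benchmarking, and a permutation test for epigenomic features near the
resulting breakpoints.

Because fragments are kilobases long, even a handful of spanning pairs
marks a junction. That makes the approach usable at low clone coverage and
for subclonal events (tumor samples where only a fraction of cells carry
the rearrangement) -- a regime the simulator exposes directly through its
`tumor_fraction` parameter.

## The insert-size model

`insert_size_model()` works on intra-chromosomal pairs only. The insert
size of a pair is its **outer distance**: rightmost mapped end minus
leftmost mapped start. This definition is standard for long-insert
libraries and is monotone in the true fragment length.

The **expected orientation** is inferred, not hard-coded: it is the
majority orientation signature among intra-chromosomal pairs, restricted
to pairs whose outer distance is at most 10x the median so that
deletion-spanning stragglers cannot sway the vote. Inference rather than a
platform constant keeps one code path for forward/reverse and mate-pair
chemistries; a user can force bounds (and the CLI can force both bounds)
when the library is known.

The consistent range `[i_min, i_max]` is the 0.5 and 99.5 **nearest-rank
percentile** (the `ceiling(p*n)`-th order statistic) of the insert
distribution over expected-orientation pairs. Nearest rank is
deterministic and integer-valued; there is no interpolation ambiguity, and
the implementation is checked against `quantile(type = 1)` as an
independent oracle. By construction ~1% of genuinely concordant pairs fall
outside the bounds; everything downstream must tolerate that tail (see
*Recovery experiments* below). Explicit `override` bounds are taken
verbatim; the histogram is still computed so diagnostics remain available.

A pair is then **consistent** iff it is intra-chromosomal, in the expected
orientation, and has `i_min <= insert <= i_max`. Failures are labelled
with the first failing reason in the order `inter_chromosomal`,
`orientation`, `too_close`/`too_far`; the reasons partition the
inconsistent set exactly.

## Orientation signatures are side-based

A signature is the ordered pair of read strands in *genomic side order*:
the strand of the upstream (5'-ward) read, then the strand of the
downstream read -- `"+-"` for a concordant inward-pointing pair. Ordering
by genomic side rather than by read role (first/second of pair) matters:
either strand of a physical fragment may be sequenced, so the role-based
encoding splits every physical orientation into two mirror variants.
Keyed on roles, half of a perfectly normal library would look
orientation-discordant, and the two junctions of a reciprocal
translocation -- which share reference coordinates but differ in which
flanks they join -- would be indistinguishable. The side-based encoding is
the BEDPE `strand1`/`strand2` convention; it yields four intra-chromosomal
classes (`+-` concordant, `++`/`--` inversion edges, `-+` everted) and
cleanly separates reciprocal translocation junctions. For
inter-chromosomal pairs side order follows the sequence dictionary.

## Clonal deduplication

PCR/optical duplicates carry identical coordinates on both ends. Pairs are
collapsed on the key `(chrom, start, strand)` of both ends, keeping the
lexicographically smallest pair id; the operation is idempotent and
order-independent. Deduplication runs before everything else, so the
percentile bounds are computed on deduplicated pairs (the alternative
ordering is defensible; this one prevents amplification artefacts from
sharpening the distribution artificially).

## Clustering discordant pairs

Calling proceeds per canonical chromosome pair (sequence-dictionary
order; side A on the lower-ranked chromosome, and for intra-chromosomal
pairs on the smaller start).

1. **Signature split.** Pairs with different orientation signatures can
   never support the same junction, so each bucket splits by signature
   first.
2. **Coarse greedy sweep.** Within a signature, pairs sorted by
   `(startA, startB)` are swept with a window `w > i_max` (default
   `2 * i_max`). A pair joins an open cluster when its side-A start is
   within `w` of the cluster's side-A start footprint and its side-B
   start within `w` of the side-B footprint; a cluster closes once the
   sweep passes it by more than `w`. When a pair matches several open
   clusters they are *merged*. Merging is the one non-obvious choice: it
   guarantees that a coarse cluster is always a union of single-linkage
   components, so the refinement step can reproduce those components
   exactly instead of being at the mercy of sweep tie-breaking.
3. **Single-linkage refinement.** Each coarse cluster is re-clustered
   under the distance `d(p,q) = max(|dA|, |dB|)` (Chebyshev on the two
   side starts), cut at `refine_cut` (default `i_max`): two pairs from one
   physical junction must have both ends within one insert length.
   Refined clusters are the connected components of the threshold graph,
   verified against a brute-force oracle on random buckets.

The result is deterministic, invariant to input record order and to any
batching of the input, which the suite asserts by permuting and
re-batching real datasets.

### Support, the 50 bp rule, and classification

Within a refined cluster, **effective support** is computed by greedy
thinning in `(startA, startB, id)` order: a member is redundant iff *both*
its side-A and side-B read starts lie strictly within `min_end_spread`
(default 50 bp) of an already-kept member -- diversity on either side
counts as independent evidence, and reads exactly 50 bp apart qualify
("at least 50 bp apart"). A call is emitted iff the effective support
reaches `min_support` (default 3). The alternative reading of the rule --
a veto on clusters without end diversity, with raw support counted -- is
available as `end_spread_mode = "veto"`.

Variant classes follow a rule table: different chromosomes give a
translocation; a non-expected signature on one chromosome gives an
inversion-type orientation anomaly; the expected signature gives a
deletion when the footprint-midpoint span exceeds `i_max` and an insertion
below `i_min`. A subtlety: the span is measured between footprint
midpoints, so a cluster assembled from marginal-tail inserts (just past
the percentile bounds) can present an in-range span that fits no class.
`classify_variant()` treats that as an internal error; the pipeline
catches it, drops the cluster, and counts it in the stage log rather than
emitting an unclassifiable call.

Footprints are the exact min-start/max-end of the member reads on each
side, reported as 0-based half-open BEDPE.

## Breakpoint set algebra

Two breakpoints `chrA:[b1,e1]-chrB:[b2,e2]` and primed counterparts
overlap iff they connect the same chromosome pair and, per side, the
minimum of the four endpoint distances
`min(|b-b'|, |e-e'|, |b-e'|, |e-b'|)` is at most `I_max`; when two
experiments are compared, `I_max` is the larger of their insert bounds.
The predicate is symmetric and reflexive but *not* transitive, so
`intersect_sv_sets()` evaluates it pairwise (an interval index generates
candidates; padded side-A footprints provably cover every
endpoint-proximal pair, and the exact formula filters them) and never
chains overlaps. Intersection is defined on the first set's elements;
swapping arguments gives the other direction. Variant class is ignored by
the predicate -- the formula is class-blind -- and germline/somatic triage
(`triage_somatic()`) inherits that behaviour: a tumor breakpoint
overlapping any panel breakpoint of any class is germline-like.

`benchmark_curve()` sweeps the minimum-support threshold and records total
retained calls (the conventional surrogate for an unknowable
false-positive rate) against truth breakpoints recovered; both are
non-increasing in the threshold. Note that `true_positives` counts *truth*
entries, so with redundant truth rows (e.g. the two coordinate-coincident
junctions of an inversion) it can legitimately exceed the retained call
count; against a non-redundant truth set it cannot.

`report_multiple()` reports, per breakpoint, overlap counts against every
other input set and gene names within `gene_window` (default 2000 bp,
distance zero meaning direct overlap) of either footprint.

## Enrichment around breakpoints

Each breakpoint contributes the midpoints of its two footprints as loci;
when the two windows of an intra-chromosomal breakpoint overlap they merge
into a single locus, so a short deletion is not double-counted. Footprints
are insert-scale wide while the default radius is 50 kb, so midpoints lose
nothing material. The observed statistic is the number of
(feature, locus-window) incidences within `radius` (windows clipped to
chromosome bounds); multiplicity keeps the statistic additive over
breakpoints, and a `unique_features` mode counts distinct features once.

The null re-places every locus uniformly on its own chromosome, keeping
per-chromosome locus counts and the feature track itself fixed -- the
track's spatial clustering is the main driver of spurious enrichment, and
this null preserves it. Fold enrichment is observed over null mean; tail
p-values use the add-one rule `(1 + #extreme) / (n_perm + 1)` (never zero;
floor `1/(n_perm+1)`, below 0.05 at the default `n_perm = 1000`). Both
tails are always reported, since depletion of a repressive mark is as
interpretable as enrichment of an active one. Calibration under a fully
independent breakpoint/feature model is asserted to sit inside the exact
binomial 99% envelope of the nominal level in the acceptance suite.

`enrichment_matrix()` evaluates every (track, sample) cell with the same
seed, so identical inputs give identical columns;
`discriminating_features()` compares group fold-enrichment vectors per
track with a rank-sum test by default (a t-test is available; it requires
two samples per group, while the rank-sum route allows -- with a warning --
singletons) at `alpha = 0.05`, optionally gated on a minimum ratio of
group means such as 1.25.

## The simulator

`simulate_mate_pairs()` is a coordinate-level generator: no sequence, no
aligner. A donor genome is built from reference-coordinate blocks
(deletions remove blocks, insertions add novel unmappable blocks,
inversions flip block strand, reciprocal translocations exchange
chromosome arms). Fragments with truncated-normal lengths
(`insert_mean = 5000`, `insert_sd = 300`, truncation at 4 sd -- the
0.5-99.5 percentile range of the defaults sits inside 4-6 kb) are placed
uniformly on the donor, drawn from the variant haplotype with probability
`tumor_fraction`; 50 bp reads at the fragment ends map back through the
block map to reference coordinates and strands. Reads that would straddle
a block boundary or land in novel sequence are resampled, mimicking the
uniquely-mapped input contract, and either fragment strand is sequenced
with equal probability. Clonal duplicates and uniform chimeric noise pairs
are appended at configurable rates. Truth records every planted junction
(two per inversion and per reciprocal translocation) with its realized
spanning-pair ids, side strands, and footprints; `expected_spanning_rate()`
gives the Poisson rate implied by the configuration, with the insertion
window shortened by the inserted length.

What the simulator does *not* emulate: mapping errors and ambiguity,
GC/mappability bias, chromatin-driven fragment bias, split reads, copy
number. Passing tests therefore demonstrate algorithmic correctness on
clean mappings, not end-to-end performance on real libraries.

## Recovery experiments and problem sizes

The acceptance-level experiments run on a 20 Mb genome (8 x 2.5 Mb), 50
planted variants across all four classes, 40,000 pairs (~10x clone
coverage), 5% clonal duplicates, and no chimeric noise; the low-purity
variant repeats this at `tumor_fraction = 0.3` over multiple seeds. These
sizes exercise every code path (hundreds of discordant pairs, ~65
junctions) while keeping the whole suite in well under a minute of
simulation time.

In these experiments the caller receives the simulator's true
fragment-length support (mean +/- 4 sd) as override bounds. This is a
deliberate separation of concerns: ground truth defines concordance by the
true bounds, and with estimated percentile bounds the 1% tail of genuinely
concordant pairs occasionally assembles into marginal clusters that no
caller could distinguish from signal -- so zero-false-call assertions
would measure the estimator's tail, not the clustering. The percentile
estimator is validated separately (exact closed-form fixture; >=98.5%
bracketing on simulated data), and the CLI test exercises the
estimated-bounds path end to end.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open everywhere internally; conversion
  happens only at the SAM/BED boundaries (1-based inclusive).
- Canonical chromosome order is the SAM sequence dictionary, with a
  lexicographic fallback for names outside it.
- Ties in the thinning scan and cluster sweeps break on
  `(startA, startB, pair_id)`; all sorts use radix order for
  locale-independence.
- Pairs whose two ends have identical coordinates are dropped with a
  counted warning (unusable for junction inference).
- A SAM/BAM stream with no alignment records is an error; records but no
  usable pairs yields an empty collection plus a populated skip report.
- `fold` is `NA` when the permutation null mean is zero (no feature mass
  reachable); p-values remain defined.
- Monte-Carlo p-values never reach zero by construction.

## Known limitations

- Breakpoint resolution is insert-scale (footprints, not base pairs);
  there is no split-read or assembly refinement.
- The enrichment null is uniform per chromosome; no GC or mappability
  matching.
- The overlap predicate has no reciprocal-overlap-fraction mode, and no
  VCF BND emission is provided.
- `benchmark_curve()` uses total calls as the false-positive surrogate;
  with a redundant truth set its `true_positives` can exceed the retained
  call count (see above).
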