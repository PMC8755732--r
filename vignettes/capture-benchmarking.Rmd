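---
title: "Benchmarking whole-exome capture protocols with wesbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking whole-exome capture protocols with wesbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wesbench)
```

## What this package computes

Comparisons of exome-capture kits and enrichment protocols rest on a
small set of evaluation computations applied to the outputs of a standard
alignment-and-calling pipeline: how much target space two probe designs
share with each other and with the coding exome; how evenly multiplexed
pools distribute data over samples; how completely the targets are
covered at useful depths; how coverage depends on target GC content; and,
for replicate libraries of a reference genome with a high-confidence
truth set, how accurately small variants are recovered. `wesbench`
implements those computations as composable functions over plain
data-frame containers, reading the standard interchange formats
(BED, VCF, bedGraph, TSV) that upstream tools emit. It deliberately does
*not* align reads, mark duplicates, or call variants — those steps belong
to bwa, Picard and bcftools; their summarized outputs are this package's
inputs.

## Coordinate conventions

Interval sets use the BED convention throughout: 0-based, half-open
`[start, end)`. VCF positions are 1-based and are converted to the BED
frame at exactly one boundary, inside `filter_variants()`, when a variant
position is tested for target membership. Chromosome-name dialects
("chr1" vs "1") differ between vendor BED files; readers harmonize them
at read time (default: strip the `chr` prefix).

Region counts and median region sizes are reported over *raw* BED records
(vendors describe their kits that way), while total bases are always
computed over merged intervals so overlapping records are not counted
twice. Book-ended intervals are merged during normalization because
base-level semantics cannot distinguish them from a single interval.

## The three-way design Venn

`venn3()` partitions the union of two capture designs and an exon track
into the seven disjoint regions of a three-set Venn diagram, by exact
base counting (GenomicRanges arithmetic underneath). Published design
comparisons print two kinds of percentages without saying so explicitly;
back-calculating from their printed base counts shows that unique and
triple-overlap percentages are taken relative to the *three-way union*,
while pairwise-overlap percentages are taken relative to the
corresponding *pairwise union*. `venn3()` computes and labels both
conventions rather than guessing a single one.

## The joint SNV/indel confusion matrix

Variant benchmarking here treats SNV and indel detection as one joint
classification task over genomic sites, not two independent tasks. A
call matches a truth record only if chromosome, position, ref, alt and
genotype all agree (genotype sensitivity can be switched off). Every
call lands in exactly one category:

* **in PG** — exact match, tallied by the call's class;
* **not in PG** — no exact match, but the position holds a truth record
  of the *other* class (an SNV called where the truth has an indel, or
  vice versa);
* **sample-specific** — matches nothing in the truth set.

Truth records never matched are **PG-specific**. From these tallies the
six accuracy statistics are:

$$\mathrm{sens}_{SNV} = \frac{InPG_{SNV}}{InPG_{SNV} + NotInPG_{SNV}},
\qquad
\mathrm{prec}_{SNV} = \frac{InPG_{SNV}}{InPG_{SNV} + NotInPG_{indel}},$$

symmetrically for indels, with F the harmonic mean per class. Two
properties of these formulas deserve emphasis, because they differ from
hap.py-style evaluation: the sensitivity denominator does *not* include
missed truth variants (PG-specific records), and the precision
denominators cross classes — both are consequences of deriving all six
statistics from the same joint confusion matrix. They are implemented
literally; `standard_metrics()` provides the conventional
TP/(TP+FN), TP/(TP+FP) recall and precision on the same tallies for
comparison, and is never silently substituted.

Indel representations are minimally normalized on construction (shared
suffix trimmed, then shared prefix trimmed down to one anchor base, with
the position advancing), so equivalent spellings compare equal. Full
left-alignment against a reference sequence is out of scope: call sets
and truth sets compared here come from the same caller, so their
representations already agree, and no reference FASTA is required.
Position matching for indels uses the anchor base.

## Filtering

The call-set filter keeps records with `DP > 13` and `QUAL > 20` by
default — strict inequalities, so a variant covered by exactly 13 reads
is removed — and optionally restricts to target regions. Records with
missing DP or QUAL fail the corresponding threshold. Thresholds and
strictness are configurable; `QUAL > 30` is a common stricter choice.

## Concordance (IoU)

`iou()` is the Jaccard index over variant identity keys; the key includes
the genotype by default (a flag disables this). Class-restricted
heatmap matrices (insertions or deletions only) filter records *before*
forming unions and intersections. Degenerate conventions: two empty
filtered sets have IoU 1 (identical emptiness), one empty set gives 0 —
this only matters for toy fixtures with no variants of a class.

## Coverage, GC bias, pool balance

`coverage_summary()` computes mean target coverage and covered-at-depth
fractions (depth ≥ N, the Picard "covered ×N" convention) from
constant-depth runs in bedGraph semantics; target bases absent from the
profile count as depth zero. `gc_depth_grid()` implements the GC-bias
density procedure: per-target (GC, mean depth) points inside the open
rectangle (0, 1) × (0, 1000) are counted on an evenly spaced 200 × 100
grid — 200 bins along GC, 100 along depth, matching the order in which
the bounds are stated — and the counts are min–max normalized to [0, 1].
Boundary points are excluded because the rectangle is open.
`pool_quantile()` returns the empirical quantile function of per-sample
data totals, the max-minus-min imbalance delta, and
`fraction_below(x)` with a strictly-less-than convention.

## The synthetic-data generator

Every stage is testable without downloads because the generator produces
all the inputs the pipeline consumes, at desk scale:

* **Targets** (`sim_targets()`): disjoint intervals with lognormal sizes
  (median 210 bp by default, as vendor designs report) and per-target GC
  from a bimodal normal mixture (means 0.38 and 0.55), emulating the
  bimodal GC distribution of human coding exons.
* **Truth sets** (`sim_truth()`): Poisson counts at 950 SNV/Mb and
  55 indels/Mb — chosen so a fully covered human-exome-sized target
  (~60 Mb) yields the ~57 000 SNVs and ~3 000 indels a deeply sequenced
  reference sample produces — placed uniformly over target bases without
  position collisions; 60% heterozygous.
* **Call sets** (`sim_calls()`): each truth variant is missed with
  probability `miss_rate`; emitted calls are class-swapped
  (SNV ↔ indel at the same position) with probability `type_swap_rate`
  or genotype-flipped with probability `genotype_error_rate`; spurious
  calls arrive as a Poisson process over target bases. Spurious
  positions are rejection-sampled away from truth positions so the
  category expectations stay closed-form (`expected_confusion()`), which
  is what makes parameter-recovery testing exact.
* **Depth** (`sim_depth_profile()`): per-target negative-binomial depth
  whose mean is modulated by a GC-bias curve — a double-logistic
  multiplier, normalized to 1 at 50% GC, depressed below ~20% and above
  ~80% GC as hybrid-capture data show.
* **Pools** (`sim_pool()`): lognormal per-sample totals;
  `imbalance_sigma` controls evenness.

`sim_study()` assembles a miniature two-pool, three-protocol comparison
(three replicate libraries of a reference genome plus one control genome
per pool) and `write_study_fixtures()` exports it as BED/VCF/bedGraph/TSV
so the analysis scripts exercise the readers end to end. The three
protocol presets encode the qualitative contrasts reported for real
protocol comparisons: protocol 1 with ~5.9% duplicates and ~7.1%
off-target reads, protocols 2–3 with ~11.9% duplicates and 9.7% / 16.7%
off-target; protocol 3's pools are markedly imbalanced (lognormal sdlog
0.45 around a 13 500 Mb median, which puts roughly 40% of samples below
12 000 Mb), while protocols 1–2 are nearly even.

### The zero-error model is fully deterministic

`zero_error_model()` sets all error rates to zero *and* uses degenerate
DP/QUAL distributions (constant 60). This is deliberate: with stochastic
per-replicate depths, the DP filter would remove different calls in
different replicates and replicate IoU could not equal 1 even with no
variant-level errors. A "zero-error" condition that is supposed to
propagate perfection through the whole pipeline must be deterministic
end to end. For the same reason the parameter-recovery grid uses the
constant depth/quality model, so that filter losses do not perturb the
closed-form tallies (the filter step still runs, it just removes
nothing).

### What the generator does not emulate

No read-level simulation (no FASTQ, no sequencing-error or duplicate
mechanics — read-category counts are drawn directly from multinomial
fractions); no real human sequence content or reference FASTA; no
linkage between depth profiles and per-variant DP; no multi-allelic
sites or complex (MNV) representations. Passing tests therefore
demonstrate correctness of the *evaluation computations* under a clean
generative model, not robustness to the representational messiness of
real caller output, which is exactly the scope boundary of the package:
representation reconciliation beyond minimal trimming belongs to
haplotype-aware comparators.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
interval oracles on ≤ 100 kb toy genomes with per-base membership
enumeration; matching oracles on call/truth sets of ≤ 500 records with
the O(n·m) exhaustive comparison; parameter recovery on ~20 Mb synthetic
designs giving ~20 000-variant truth sets, 12 error-model grid points ×
5 seeds, checked against closed-form expectations at 3 binomial standard
deviations. Every generator is bit-reproducible given (parameters,
seed); study drivers fan one master seed out into per-component streams
(`fan_seeds()`) so any component can be regenerated independently.

Degenerate inputs are defined rather than left to chance: empty interval
sets are valid and normalize to themselves; an empty target set is an
error for coverage (the denominator would vanish); zero-denominator
metrics return `NA` rather than raising; two empty class-filtered
variant sets have IoU 1; `fraction_below(min)` is 0. Ties in interval
sorting cannot occur after normalization (intervals are disjoint and
non-adjacent).

## Known limitations

* The matcher requires representational agreement (same caller on both
  sides); it will under-match call sets from different callers with
  different indel spelling habits.
* The joint-task metric formulas are faithful to their printed
  definitions, which means they are *not* comparable to hap.py
  recall/precision numbers; use `standard_metrics()` for that.
* `OTHER`-class records (MNVs) are excluded from confusion tallies.
* Coverage summaries trust the depth track they are given; whether it
  was computed before or after duplicate removal is provenance the
  caller must track.
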