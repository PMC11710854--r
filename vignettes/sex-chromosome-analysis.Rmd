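---
title: "Methods: sex-chromosome analysis from depth, Hi-C, and alignments"
author: "SexChromTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-chromosome analysis from depth, Hi-C, and alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SexChromTools)
library(GenomicRanges)
```

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made
where the methods literature leaves them open.

## The setting

Sex chromosomes stop recombining with each other over most of their
length. Three consequences drive everything in this package:

* **Hemizygosity.** A male carries one X-differentiated (X-Div) and one
  Y-differentiated (Y-Div) copy against two copies of each autosome; a
  female carries two X and no Y. Sequencing depth therefore encodes
  sex-linkage.
* **Fragmentation.** X-Div, Y-Div, and the pseudoautosomal regions
  (PARs, still recombining and diploid in both sexes) often assemble as
  separate, unplaced scaffolds. Hi-C contact strength encodes which
  chromosome an unplaced scaffold belongs to.
* **Degeneration in strata.** Recombination stopped in discrete events;
  each "stratum" has diverged between X and Y since its own stop date,
  so X/Y alignment identity dates the events.

## Sex-linkage from depth ratios

Depth is averaged in 5-kb windows (`depthWindow`) and normalized by the
*peak* coverage: the mode of the 1x-binned depth histogram, restricted to
bins above 0.25x the maximum so that zero-inflated and hemizygous windows
do not capture the mode. The mode, not the mean, is used because
sex-linked sequence skews the mean downward; the reported peak is the
median within the modal bin so that a constant track normalizes to
exactly 1.

The per-window statistic is the pseudocounted ratio
`(f + c)/(m + c)` of normalized female to male depth with `c = 0.05`
(normalized-depth units) and a cap at 10; the pseudocount keeps windows
where the male has no coverage finite, and the cap bounds the influence
of female-only windows. Scaffolds longer than 10 kb are called X-linked
when over 60% of usable windows fall in the closed band [1.5, 2.5], and
Y-linked for [0.0, 0.3]. Band endpoints are treated as inclusive — the
method tradition says "between" without specifying — and both endpoints
and bands are arguments. With the 60% rule and disjoint bands a scaffold
can never satisfy both calls.

PAR delineation inside a sex-linked scaffold is automated rather than
done by eye: windows in the band [0.75, 1.25] are labelled
pseudoautosomal, labels are smoothed by majority vote over 5 windows, and
maximal runs of at least 10 windows (50 kb) are reported, snapped to
window boundaries. Automating this costs a window or so of boundary
precision but makes the call reproducible; on clean simulations the
boundary lands within one window of truth.

## Hi-C assignment of unplaced scaffolds

The assumption is the standard one: intra-chromosomal contact strength
exceeds inter-chromosomal strength. For a candidate chromosome, the
scaffold's bin-pair strengths against that chromosome are compared with
its strengths against every competitor chromosome by a one-sided Wilcoxon
rank-sum test; the scaffold is assigned only if *every* competitor test
is significant at `alpha` (default 0.05 — a conventional level; the
method tradition says only "significantly"). No multiple-testing
correction is applied across competitors: the all-competitor conjunction
is already conservative, and correcting would only make it more so.

A PAR candidate is tested against a chromosome *pair*: its profiles with
the two members are pooled into one dataset ("its interaction with X and
Y" treated as one sample) and the pooled set must beat every competitor.
A per-chromosome AND variant (`pooled = FALSE`) requires each member
separately to beat every competitor; it is stricter, and it is the
variant that rejects a scaffold enriched with only one member of the
pair when the scaffold's true home chromosome is inside the pair.
In pooled mode that protection comes from the competitor set, which
should contain every anchored chromosome. Raw strengths are accepted
without balancing: the test is rank-based, so any monotone normalization
(including a global rescaling) leaves decisions unchanged, which is also
asserted as a test.

The rank-sum p-value is exact (by enumeration) when the two samples
together hold at most 16 values without ties, and a tie- and
continuity-corrected normal approximation otherwise; at n = m = 8 the
approximation stays within 0.01 of the exact enumeration.

## Gap-closure auditing

A gap is a maximal N-run. Gaps under 5 bp, or within 200 bp of a
scaffold end, are excluded. The 500-bp flanks on each side are mapped
onto the new assembly; the audit then applies, in order: both flanks on
one scaffold with consistent orientation and order and no N in the
intervening sequence — `closed`; flanks on two scaffolds —
`trans_scaffold_break`; anything else (unmapped flank, inconsistent
geometry, N in between) — `open`.

Three rules are decided here because the tradition leaves them silent:
the *aligning rate* is defined as the fraction of flank bases inside the
aligned block (identity is not separately thresholded; the >0.70 cutoff
applies to the rate); orientation and order consistency is required for
`closed`, since without it an inversion breakpoint would count as a
closure; and the intervening span is capped at 1 Mb to guard against
spurious distant hits.

The built-in mapper is a seed-and-extend aligner for the synthetic and
small-genome case: exact 31-mer seeds every 8 bp, co-diagonal clustering,
then a local alignment (match 2, mismatch −3, gap open 5, extend 2) of
the flank against the best-supported window, both strands, ties broken
by match count, then identity, then leftmost coordinate. At 10% random
substitution it recovers planted flanks in ≥95% of trials. Production
use can supply externally computed hit tables instead (`flankHits`).

## Ampliconic regions: three channels

**Palindromes** come from inverted self-alignment segments (strand "−",
query left of target, trivial diagonal removed). Segments whose arm
projections are co-linear within a 2-kb chain gap are chained — the gap
default is an exposed parameter; published palindrome pipelines differ
here — and chains must satisfy: identity ≥ 0.98, both arms ≥ 8 kb,
spacer ≤ 500 kb, repeat content of the span < 0.80. Overlapping
candidates are deduplicated keeping the longer arm.

**Arrays** scan the provided sex-linked sequences (not the genome — the
windows are enumerated over the sequences given, the narrower reading of
an ambiguous protocol) in 5-kb windows with 2-kb overlap. A window is a
candidate when a self-hit with identity > 0.99 covers more than half of
it; hits whose *target* overlaps the window itself are discarded as
self-locus hits, which any self-alignment protocol implies. Candidates
merge; merged runs under 10 kb are dropped. A single candidate window
suffices before merging (no consecutive-window requirement).

**Depth excess** finds amplicons collapsed during assembly: a non-PAR
sex-linked 5-kb window whose GC-corrected male depth reaches the
autosomal reference (`>=`, deliberately inclusive) with repeat content
< 0.80. The autosomal reference is the *mean* corrected autosomal window
depth (median available); hemizygous sequence at half the autosomal
level cannot reach it by noise at realistic depth, while a two-fold
collapsed region sits at or above it.

GC correction is binned-median scaling: windows are grouped into GC bins
of width 0.01, each value is multiplied by `globalMedian/binMedian`, and
bins with fewer than 20 windows borrow the nearest populated bin's
factor. On a genome with both diploid and hemizygous sequence the bias
must be estimated on copy-number-stable sequence, so `referenceSeqs`
(typically the autosomes) restricts the bin medians while the factors
apply genome-wide. This is simpler than a read-level GC model and
equivalent in expectation for window-level data.

The three region sets are merged by union; every output region is
annotated with the channels contributing at least one base, and genes
with more than 80% of their length inside merged regions are called
ampliconic, excluding olfactory and vomeronasal receptor families by
name pattern (they amplify genome-wide and are not sex-specific). The
copy-number figure attached to a call is `round(median corrected gene
depth / (autosomal reference / 2))` — an estimate labelled as such, for
hemizygous non-PAR genes.

## Strata divergence and ages

X/Y identity per 1-kb X window is matched bases over aligned columns
intersecting the window. When only segment-level identities are
available, matches over a partial overlap are apportioned uniformly
(overlap × identity), which conserves the total match count exactly; the
conservation is asserted as a test. An X/Y segment is dropped when its Y
span (≥50% reciprocal overlap) aligns to autosome or PAR with *strictly*
higher identity and *strictly* longer alignment — ties keep the segment,
reading "higher and longer" literally.

Divergence of a concatenated stratum alignment uses the Jukes–Cantor
correction `d = -(3/4) ln(1 - 4p/3)` over valid columns (both non-gap,
non-N, unmasked; masks carry the coding and repeat exclusions, taken as
the union when annotations conflict). The 95% CI is the percentile
interval of 1,000 bootstrap replicates drawn by resampling *columns*
with replacement — the site-bootstrap convention; replicates that reach
JC69 saturation (p ≥ 0.75) are discarded and counted. The estimator
saturates as p approaches 0.75, so CIs widen sharply for very old
strata.

Ages follow from a male-mutation-bias rate model. With α the
male/female germline mutation-rate ratio and rates
A = (α+1)/2·μ_f, X = (2+α)/3·μ_f, Y = α·μ_f, X/Y divergence accumulates
at `(2+4α)/(3+3α)` times the autosomal divergence rate — a ratio bounded
in (2/3, 4/3), equal to 1 only at α = 1, and increasing in α. Then
`μ_XY = ratio · μ_AA` and `T = d/μ_XY`; CI endpoints divide likewise.
At the monotreme working values α = 2.95 and μ_AA = 7×10⁻⁹/site/year,
μ_XY = 8.15×10⁻⁹/site/year. Stratum intervals are inputs: calling
stratum *boundaries* needs gametolog phylogenies and synteny inspection
and is out of scope.

## The synthetic-data generator

`simulateScenario()` builds the reference study conditions at a scale
where every stage runs in seconds. Geometry (all configurable): three
400-kb autosomes; X1 = 150-kb PAR + three 100-kb strata + 150-kb
X-specific tail, Y1 = the same PAR and strata + 100-kb Y-specific tail;
a second pair X2 (400 kb) / Y2 (300 kb) whose 200-kb PAR is an
*unplaced* scaffold, mirroring the situation where a PAR cannot be
identified by depth and must be rescued by Hi-C; and an unplaced 150-kb
X-Div fragment. Planted features: a palindrome on Y1 (12-kb arms, 10-kb
spacer, ~99.5% arm identity), a 6 × 5-kb tandem array on X2 (~99.5%
inter-copy identity), a collapsed 4-copy amplicon on Y1, and two
negative decoys — a 7-kb-arm inverted repeat at ~98.5% identity (above
the palindrome identity cutoff, below the arm-length and array-identity
cutoffs, so only the arm rule rejects it) and a fully repeat-annotated
palindrome on an autosome.

Strata sequences descend from a common ancestor with JC-style
substitutions at half the planted divergence on each branch; since the
per-branch process is exactly a Jukes–Cantor transition matrix, the
X-to-Y mismatch expectation equals the JC expectation at the full
divergence. Default divergences are 0.05, 0.20, and 0.652 — young,
intermediate, and old enough to probe the nonlinear part of the
correction while staying clearly below saturation.

Depth is negative-binomial on per-window *read counts*: mean
`depthMean · cn/2 · window/readLength`, dispersion 0.005, read length
150 bp. At the default 30x this gives a per-window coefficient of
variation near 8%, the right order for real short-read coverage in 5-kb
windows. The female Y mean is not zero but a 2% contamination floor
(`femaleYFloor`) so ratio denominators behave as they do with real
index-hopping and mismapping. GC content varies sinusoidally
(0.42 ± 0.08, 60-kb period) and biases depth linearly (±12% across the
range), giving the GC-correction stage a real signal to remove; the GC
track is measured from the emitted sequence, not copied from the plan.

Hi-C strengths follow `(d/resolution)^-1` within a chromosome (distance
`d` computed from each scaffold's truth placement, so unplaced
scaffolds carry their home chromosome's profile and the unplaced PAR
carries both of its pair), an inter-chromosomal baseline of 0.02, and
10% log-normal noise. The resolution default is 25 kb — the bin count
per scaffold at this genome scale then matches what a 100-kb resolution
yields on full-size chromosomes. No matrix balancing is modelled; the
assignment test is rank-based.

The assembly pair plants 10 closed, 5 open, 5 trans, and 2 excluded
gaps (one under 5 bp, one 150 bp from a scaffold end), each realized
literally: closed gaps get contiguous fill, open gaps lose a flank,
trans gaps split their flanks across scaffolds. The expression matrix
plants 20% testis-specific genes (testis ~200 TPM against <0.5
elsewhere) among broadly expressed genes with log-normal tissue scatter
(sd 0.3), which keeps housekeeping τ near 0.4–0.6 — the empirical range
— and specific genes near 1.

Everything is deterministic: one integer seed drives the genome, and
fixed offsets derive the depth, Hi-C, assembly, and expression streams,
so the same config yields byte-identical files on any platform (sorting
uses radix order to avoid locale dependence).

**What passing tests do and do not show.** The generator emulates copy
number, contact decay, substitution divergence, and planted feature
geometry. It does not emulate mapping artefacts, repeat-driven
multi-mapping, segmental duplications other than the planted ones,
Hi-C ligation noise, gapped X/Y alignment (planted alignments are
substitution-only), or expression quantification noise. Perfect recovery
on these scenarios therefore demonstrates correctness of the decision
rules and estimators, not robustness to real-data artefacts; thresholds
retain the values from the methods tradition rather than values tuned to
the simulations.

## Numerical choices and degenerate inputs

* Interval algebra is `GRanges`-based (1-based, closed); 0-based
  half-open coordinates appear only in file readers/writers.
* `mergeIntervals(maxGap = 0)` fuses overlapping *and bookended*
  intervals; an all-zero depth track, an empty profile, a scaffold with
  no usable windows, and a zero-column alignment each raise or warn
  explicitly rather than propagating NaN.
* Window counts follow `ceiling((len - window)/step) + 1` with the last
  window truncated; a sequence shorter than one window yields a single
  truncated window.
* The tau index is computed on linear TPM after replicate averaging
  (log2 transform available); an all-zero profile is NA, a tie at the
  maximum makes a gene non-specific, and the specificity threshold
  (default 0.8) is deliberately exposed because no standard cutoff
  exists.
* Bootstrap and simulation problem sizes in the tests — 10-kb alignment
  columns with B = 1000 and 100 trials for CI coverage, 2,000–6,000
  windows for depth laws — were chosen as the smallest sizes at which
  the asymptotic claims under test are expected to hold.

## Limitations

* The flank mapper is exact-seed based: it will miss a flank whose every
  31-mer is disrupted (~>15% divergence); supply external hits for
  diverged assemblies.
* Copy-number estimates are depth ratios rounded to integers; they are
  indicative, not genotyping.
* Palindrome chaining is greedy and single-pass; heavily nested inverted
  repeats may chain suboptimally.
* Strata dating assumes a molecular clock and the JC69 model; at
  divergences approaching saturation both assumptions dominate the CI.
* PAR delineation assumes depth ratios switch cleanly at the boundary;
  degenerating ("young stratum") sequence with intermediate ratios will
  blur it.
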