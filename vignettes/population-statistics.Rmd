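---
title: "Quantifying sequence-discrete populations from read recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sequence-discrete populations from read recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magpop)
```

## The problem

Marine microbial communities are organized into *sequence-discrete
populations*: when metagenomic reads are recruited to a genome bin (MAG),
reads from the population itself pile up at high nucleotide identity while
reads from co-occurring relatives sit several percent lower, separated by a
coverage gap of orders of magnitude. `magpop` implements the statistics used
to quantify such populations through a seasonal metagenome time series —
how deep each genome is sequenced, what fraction of the community it
represents, where its identity boundary lies, and how clonal it is — plus
the genome dereplication needed to pick one representative per population,
and a ground-truthed simulator to validate the whole chain.

## Depth and TAD

Per-base depth comes from recruited alignments (12-column tabular, the
BLAST `-outfmt 6` dialect). Subject intervals are normalized once, at the
file boundary, to 0-based half-open coordinates with an explicit strand
flag; all interval arithmetic downstream uses that single convention.

The **truncated average depth** `tad(profile, central_fraction = 0.8)`
concatenates the per-base depths of all contigs (zero-coverage bases
included), sorts them, drops `floor(((1 - central_fraction)/2) * L)`
positions from each tail, and averages the rest. TAD80 (the default)
discards the top and bottom 10% of positions, which damps the two dominant
artifacts of MAG coverage: pile-ups on conserved regions (top tail) and
contig edges or mis-binned fragments (bottom tail). Two conventions are
deliberate:

* zero-depth positions count — the statistic describes *all* genome
  positions, not just covered ones;
* contigs are pooled before sorting, so a short, poorly covered contig
  cannot dominate its own trimmed mean. The truncation count uses `floor`
  per tail (with a numeric guard so that binary representation of
  `1 - 0.8` cannot change the count), which makes the statistic
  deterministic for any profile length.

## Marker normalization and relative abundance

A universal single-copy gene (rpoB in the motivating survey) occurs once
per genome, so the pooled sequencing depth of that gene across the whole
community estimates the summed depth of all genomes. `marker_depth()`
divides total aligned bases on the marker references by the mean reference
length; `relative_abundance()` is then simply `TAD / marker depth`, the
fraction of the community the population represents. The mean reference
length is used as the denominator because the upstream classifier pools
hits across reference variants; any single-scalar summary is equivalent up
to a constant, and the mean is robust to the size of the reference set.

Detection uses a strict inequality, `abundance > 1e-4` (0.01% of the
community, about 2x coverage at the sequencing depths this rule was
calibrated for). Prevalence (percent of samples where a genome is
detected) is reported to one decimal by *truncation*, which is the
convention the published survey numbers follow (25/38 prints as 65.7).

## Recruitment plots and the population cutoff

`identity_histogram()` bins aligned bases by percent identity (default
0.5% bins over [70, 100]; a value exactly on an edge joins the upper bin,
100% joins the top bin), normalized by genome length so bins read as
depth. `recruitment_matrix()` adds the genome-position dimension, assigning
each alignment to the position bin of its midpoint so no alignment is
counted twice.

`detect_cutoff()` automates the visual rule used on recruitment plots.
With `P` the peak bin depth and threshold `P * 10^-drop_orders`
(default three orders of magnitude):

1. scan from the peak toward lower identity;
2. the gap opens at the first run of at least `min_gap_bins` (default 2)
   consecutive bins below the threshold;
3. a discontinuity is declared only if depth re-emerges to at least the
   threshold on the far side of the gap;
4. the cutoff is the lower edge of the last above-threshold bin before the
   gap. If no gap is found, or nothing lies beyond it, the configured
   `floor` (default 95) is returned with `discontinuity_found = FALSE`.

Two details merit explanation. *Why a minimum gap width?* Fixed-length
gapless reads can only realize identities on a lattice with spacing
`100/read_length` (0.67 points for 150 bp reads), which is coarser than
the 0.5-point bins; isolated structurally-empty bins therefore occur inside
a perfectly healthy in-population tail and must not be mistaken for a
population boundary, whereas a genuine sequence-discrete gap spans several
percent identity. *Why require background beyond the gap?* A discontinuity
is a boundary between the population and other recruiting taxa; when a
population is alone, its identity tail simply decays to zero and there is
no boundary to report — the automated rule returns the floor and says so,
rather than inventing a cutoff from the shape of a binomial tail. Users
reproducing a visually chosen cutoff can bypass detection entirely with
`manual =`.

A consequence worth knowing: whether a sister population at, say, 92% ANI
produces a resolvable three-order gap depends on the read length. Per-read
identity against the sister reference varies with standard deviation
`100 * sqrt(p(1-p)/R)` (`p` the per-base difference rate, `R` the read
length). At `R = 150` that SD is about 2.3 points and the sister's upper
tail floors the valley near `2e-2` of peak — no 10^3 drop exists to be
found at equal depth. At `R = 400` (the long-read end of the mixed
454/Illumina series the simulator emulates) the valley floor is around
`3e-4` of peak and the detected cutoff lands at 98, the value the visual
rule produced for the natural populations. Real short-read mappers achieve
a similar sharpening through local alignment trimming, which the gapless
model deliberately does not imitate. The packaged gap experiments
therefore use 400 bp reads, and 150 bp everywhere read-level identity
variance is the quantity of interest.

## ANIr

`anir()` averages the percent identity of alignments at or above the
cutoff. The default weights each alignment by its aligned length (a
base-weighted mean: every aligned base votes once); the unweighted
per-read mean is available via `weighting = "per_read"`. With equal-length
gapless reads the two coincide up to rounding; with real mappers the
base-weighted form is less sensitive to short spurious alignments, which
is why it is the default. Note that ANIr is conditioned on the cutoff:
reads below it are excluded, so ANIr is monotone non-decreasing in the
cutoff and always lies in `[cutoff, 100]`.

## Dereplication

Quality is scored as `completeness - 4 * contamination`; bins scoring at
least 50 (boundary included) pass the standard gate. Pairwise ANI is
estimated with MinHash sketches: the `s = 5000` smallest 53-bit hashes of
canonical 21-mers (lexicographic minimum of k-mer and reverse complement;
k-mers containing N skipped; fixed splitmix64-style mixer, so sketches are
reproducible across machines). The Jaccard index `j` on the merged
bottom-`s` set converts through the Mash distance
`D = -ln(2j/(1+j))/k` to `ANI = 100(1 - D)`; disjoint sketches are below
the estimator's resolution and return `NA` rather than a fabricated
number.

`greedy_cluster()` visits genomes in descending quality score (ties:
longer genome, then lexicographic id) and attaches each to the existing
representative of highest estimated ANI meeting the threshold (inclusive
`>=` by default, at both the 95% and 99% operating points), else founds a
new cluster. Representatives therefore maximize quality within their
cluster by construction. A single MinHash pass replaces the two-phase
sketch-then-alignment-ANI pipeline of dedicated dereplication tools: at
desk scale the sketch estimate is accurate to a few tenths of an ANI point
in the 95-100% region that decides cluster membership. One bias is worth
stating: `D` estimates `-ln(1-d)` for true divergence `d`, so the ANI
estimate is low by `100(-ln(1-d) - d)` — about 0.13 points at `d = 0.05`
but 0.54 points at `d = 0.1`. Near the clustering thresholds the bias is
negligible; it is why accuracy claims are made for `d <= 0.05` and only
the closed-form expectation `100(1 + ln(1-d))` is asserted beyond that.

## The synthetic community

The simulator emulates the statistical structure of the motivating
time-series populations, not their sequences:

* i.i.d. genomes at chosen GC (the two clades of interest sit near 50.5%
  and 37.5% GC, with ~1.9 and ~1.4 Mbp genomes; tests use 40-200 kb
  genomes, which preserves every statistic while keeping runtimes in
  seconds);
* sister clades derived by per-base substitution at a chosen divergence
  (no indels), giving known ANI;
* reads multinomially allocated with weights `abundance * genome_length`,
  uniform origins, lineage substitutions at the intra-population
  divergence `delta` (default regime 0.004) then sequencing errors at
  `epsilon` (0.001) — expected read identity `100(1 - delta - epsilon) =
  99.5`, the middle of the clonal band observed in nature (99.2-99.8);
* a marker locus of fixed length (4000 bp, an rpoB-scale gene) placed
  uniformly at random in each genome; marker reads are identified from
  provenance, mirroring an upstream classifier that has already isolated
  bona fide marker hits, and their reported intervals are clipped to the
  locus so summed aligned bases estimate marker depth without edge
  inflation;
* `truth_align()` emits one exact gapless alignment per read at its true
  origin (optionally against a sister's colinear genome for
  cross-recruitment), with identity computed by direct base comparison.

What it does **not** model — indels, quality-score error profiles, GC
coverage bias, chimeric assembly, strain mixtures within a population,
local-alignment end trimming — bounds what green tests mean: they validate
the estimators under their own assumptions, not the behaviour of any
particular mapper on real data.

## Numerical and design choices, in one place

* Truncation count per TAD tail: `floor`, with a round-to-9-decimals guard
  before flooring.
* Identity bins: half-open upward, top bin closed at 100; bin width must
  divide the domain span exactly.
* Cutoff detection: `drop_orders = 3`, `floor = 95`, `min_gap_bins = 2`;
  discontinuity requires re-emerging background at threshold depth.
* ANIr: base-weighted by default; errors (not zero, not NA) when nothing
  recruits at the cutoff.
* Detection threshold: strict `>` at `1e-4`; prevalence truncated to one
  decimal.
* Enrichment pseudocount: half the smallest nonzero proportion across both
  normalized tables (or a user-supplied number); classification at
  `log2FC > 2` (small-fraction enriched) and `log2FC < -1`
  (large-fraction enriched), mirroring the published readouts.
* Dereplication: inclusive thresholds; quality-score ties broken by total
  length then id; fixed 53-bit hash space (collision probability across a
  5000-hash sketch is ~1e-9).
* Simulator seeds: every stochastic function takes `seed` and restores the
  caller's RNG state, so fixed seeds give byte-identical FASTQ, alignment
  and truth files.

## Problem sizes used by the packaged experiments

The test and acceptance experiments run single-CPU in well under a minute
each: clonal ANIr at ~60x over a 40 kb genome (16k reads of 150 bp);
the two-population gap experiment at 50k reads of 400 bp; the
five-population abundance recovery at 30k reads (~110x pooled marker
depth); dereplication on ten 60 kb genomes in three truth groups plus a
200 kb pair for ANI accuracy. These sizes were chosen so that sampling
error sits several standard deviations inside each asserted band — larger
communities only tighten the estimates.

## Limitations

The enrichment classifier is a normalized log-ratio with a pseudocount,
not a shrinkage-based differential-abundance model: it reproduces
threshold readouts, not p-values. The dereplication step estimates ANI
from k-mer sketches only; alignment-based ANI, amino-acid identity, and
taxonomy assignment are out of scope. The cutoff detector operationalizes
a rule that was originally applied by eye; on real recruitment plots with
shallow background the automated rule is conservative (it returns the
floor rather than guessing), and the `manual` override exists precisely
for that case.
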