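---
title: "chromquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromquant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each stage of the
pipeline, the tunable parameters and their defaults, what the synthetic-data
generators do and do not emulate, and the design choices made where the
underlying protocol left the design open.

## Conventions

All coordinates are 0-based, half-open, both internally and in BED/bedGraph
I/O.  The TSS of a gene is `start` on the `+` strand and `end - 1` on the
`-` strand.  Alignment records carry a single `start` field holding the
**5' position** of the read: the leftmost base for `+` reads and the
rightmost base for `-` reads.  This makes fragment extension and duplicate
grouping symmetric: a `+` read extends to `[start, start + L)`, a `-` read
to `(start - L, start]`, and the nexus duplicate key is simply
`(chrom, strand, start)`.

All generators take an integer seed and evaluate under `with_seed()`, which
restores the caller's RNG state; a fixed seed gives byte-identical output.

## Spike-in calibration

Each sample is spiked with a fixed amount of reference-species chromatin
before immunoprecipitation.  With non-orthologous read tallies
`chip_sc`, `chip_cg`, `input_sc`, `input_cg` (Sc = target genome,
Cg = reference genome), the calibration factor is

$$ f = \frac{\mathrm{Input}_{Cg}\,\mathrm{ChIP}_{Sc}}
            {\mathrm{Input}_{Sc}\,\mathrm{ChIP}_{Cg}}. $$

The input ratio measures the mixing proportion; dividing the ChIP ratio by
it isolates the relative pull-down efficiency of target chromatin.  The
factor is invariant to multiplying all four counts by a constant, so it does
not depend on sequencing depth, and tracks are RPM-normalized *before*
scaling (the factor is depth-ratio invariant under that choice).

Design choices:

* **Orthologous reads** (aligning to both genomes) are excluded from both
  the target and the reference tally, symmetrically.  The real two-genome
  alignment cascade is out of scope; the generator emits reads pre-labelled
  `target` / `reference` / `orthologous`.
* **Fold enrichment** substitutes 1 (a value well below the genomic mean)
  for zero bins in either track before taking the ratio, so ratios are
  always defined.
* **Bidirectional significance**: per bin, the observed ChIP count is
  tested against a Poisson expectation taken from the control track (scaled
  to ChIP depth, zero-substituted): enrichment is the upper tail
  `P(X >= obs)`, depletion the lower tail `P(X <= obs)`.  Each direction is
  converted to q-values by Benjamini–Hochberg across all bins, and the
  direction with the larger `-log10(q)` is reported.  Ties break to
  `enriched` so output is deterministic.  BH was chosen because the
  correction used by the original track tools is not documented in detail.

## Coverage tracks and difference maps

Mononucleosome fragments are extended to 148 bp, ChIP reads to 200 bp, from
the 5' position in the 3' direction, clipped at chromosome edges; per-base
coverage is the count of overlapping extended fragments, averaged within
bins when `bin_size > 1`.  Pile-up conserves mass: total coverage equals the
summed clipped fragment lengths.  Difference maps are `mutant - WT` on
depth-comparable (rpm or calibrated) tracks and are therefore antisymmetric.
Replicates are compared by Pearson correlation of their binned coverage; the
merge threshold is not dictated by the protocol, so the package documents a
conventional default of r >= 0.8 and leaves enforcement to the caller.

## TSS window matrices

Signal is averaged in 20 bp windows spanning [-800, +800) around each TSS —
exactly 80 half-open windows — oriented along the gene so that window 1 is
always the most upstream.  Where the protocol's narrative mentions 50 bp
windows for display, the operative description specifies 20 bp; 20 bp is the
default and the width is configurable.  A window is **masked** when it
overlaps any base of a different gene's body (whole-window masking, not
truncation: the upstream description of neighbour avoidance does not
define a partial rule),
or when it extends past a chromosome end (masked, not an error).  Masked
cells are `NA` and excluded from mean profiles.

## ChIP-nexus preprocessing

Raw reads carry a 6 bp random barcode then a 4 bp fixed barcode before the
insert.  `strip_barcodes()` removes both, appends the random barcode to the
read id after `:`, and rejects reads whose fixed barcode does not match
exactly (0 mismatches — the upstream scripts are unpublished, so the
strictest rule is used) or that are too short (< 11 bases).  The default
fixed barcode `CTGA` is a configurable placeholder; the protocol does not
state the sequence.

After alignment, `barcode_dedup()` groups reads by `(chrom, strand, 5'
position)` — strand is included because nexus signal is strand-resolved —
and collapses reads with an identical random barcode to the best alignment:
highest mapq, ties broken by lexicographically smallest read id (the
protocol states only that the best alignment is kept).  Distinct barcodes at the
same coordinate are all retained; deduplication is per coordinate, not
genome-wide, since duplicates are defined by shared mapping coordinates.
The operation is idempotent.

## Histone turnover

RITE tags old histone H3 with V5 and new histone H3 with Flag; the turnover
signal is the Flag:V5 ratio.  Reads are assigned to the 20 bp window
containing their 5' position (nexus reads mark precise stop sites, so no
extension), summed per window, and depth-normalized.

**Depth scale.**  Normalizing each tag library by its *own* total multiplies
every ratio by the inverse genome-wide tag odds: if 30% of all reads are
Flag, per-library RPM inflates every Flag:V5 ratio by 0.7/0.3.  Because the
two ChIPs sample the same pool of nucleosomes, the package normalizes both
matrices by the **combined** total by default (`depth = "common"`), which
preserves the absolute odds `f/(1-f)` for a region with new-histone fraction
`f`; `"library"` and `"raw"` modes are available.

Ratios are `(flag + c)/(v5 + c)` with pseudocount `c = 1` normalized count
(zero handling is not specified upstream; 1 keeps sparse windows finite and
the ratio antisymmetric under tag swap with equal pseudocounts).

**Group test.**  The WT-vs-mutant contrast for a gene group is a
repeated-measures ANOVA in its simplest form: compute the group-mean
turnover per window in each condition, treat windows as matched subjects and
condition as the repeated factor.  With two conditions this reduces exactly
to the paired t-test on the per-window differences, F = t² with
df = (1, W-1).  The one-line description of the original test is ambiguous
about whether genes or windows are the repeated subject; its phrasing in
terms of corresponding windows motivates the window-paired form, fixed as
the implementation (a gene-level mixed model is deliberately not
implemented).  Its type-I error is verified at ~5% by simulation.
P-values across groups become q-values by Benjamini–Hochberg.

## Clustering and intersections

Occupancy-change matrices are clustered by Euclidean k-means with k = 6,
k-means++ seeding, and the best of `n_init = 20` restarts by total
within-cluster sum of squares (the original analysis does not specify the
initialization).  Genes with more than 50% masked windows are
dropped; remaining masked cells are imputed with the gene's row mean — a
package choice, logged per run in the returned object.  Rows are **not**
standardized by default, matching the visual semantics of occupancy heat
maps; a `standardize` flag exists.  Labels are renumbered by decreasing
cluster size (ties by centroid norm) so a fixed seed yields an identical,
stable assignment.

Gene-set intersections use the upper-tail hypergeometric probability
`P(X >= k)` (enrichment only, the usual intersection p-value), with
the universe being the clustered genes carrying a transcription-rate class
for cluster-by-rate tables.  Venn partitions are exact set algebra over any
number of sets on a shared universe.

## Stranded expression

Reads are counted per gene by their 5' position; under the dUTP-style
`"reverse"` convention (default, configurable and echoed in CLI output) a
read is *sense* when its strand is opposite the gene's.  Reads overlapping
several genes count for each by default (logged; an exclusive mode exists).
Antisense units are whole gene bodies.

The differential test is a documented stand-in for DESeq (whose internals
are explicitly out of scope), keeping what the downstream thresholds depend
on:

1. median-of-ratios size factors over the combined matrix;
2. per-gene method-of-moments NB dispersion
   (`Var(k/s) = mu/s + alpha mu^2`), shrunk toward a genome-wide common
   dispersion with `prior_df = 50` prior degrees of freedom.  The common
   value is estimated by an *unbiased ratio estimator* (summed unbiased
   numerators over summed `mu^2` weights) — a trimmed mean of per-gene
   estimates is ~20% biased low at n = 3, which makes the null
   anti-conservative;
3. a Wald test of the log2 ratio of normalized condition means (pseudocount
   0.5), referred to a moderated t with residual + `prior_df` degrees of
   freedom.  The added degrees of freedom reflect the information the
   shrinkage borrows; with them the null p-value distribution is uniform in
   simulation (aggregate KS), where a plain t(residual df) is badly
   conservative and a normal reference is anti-conservative.

Genes are called `up` when FDR (BH) is strictly below 5% **and**
log2 fold change is at least 0.585 (1.5-fold; the boundary value itself
passes), `down` symmetrically.  Note an intrinsic property of this rule: the
fold-change estimate at dispersion 0.05 with n = 3 has a standard deviation
of ~0.26 log2 units, so effects planted exactly at the 1.5-fold boundary are
recovered with at most ~50% sensitivity by *any* unbiased procedure — power
statements are only meaningful for effects clearly above the filter.

The qPCR fold change is the standard `2^(-ddCt)`:
`dCt = Ct_target - Ct_reference` per strain, `ddCt = dCt_mut - dCt_wt`.

## The synthetic world

The generators emulate, with known truth:

* a single-chromosome genome of non-overlapping genes (overlap only occurs
  where ±800 bp windows reach a neighbour, exercising the masking rule),
  each with a transcription-rate class drawn with yeast-like proportions
  (15/35/35/12/3% across the five classes);
* mononucleosome dyads drawn from a stylized promoter profile (uniform
  upstream, an NDR at [-200, -20), phased nucleosomes of 165 bp repeat with
  the +1 dyad near +74 decaying into the body), 148 bp fragments, with the
  mutant's sampling weights multiplied by `2^delta` for a planted log2
  occupancy-change matrix; 10% of fragments are unpositioned background;
* spike-in ChIP/input mixtures with target:reference mixing 2:1 (from the
  stated 40e7:20e7 cell counts; exposed as a parameter since the molar
  ratio is not stated), a 5% orthologous fraction, and a global ChIP
  scaling applied to target pull-down only — so RPM tracks are blind to it
  by construction while the calibration factor recovers it;
* barcoded RITE reads whose Flag/V5 tag is drawn from the *locus'* planted
  new-histone fraction (promoter windows [-300, 0) vs gene body; 0.5
  outside windows), with a `dup_rate` fraction of exact
  coordinate-and-barcode copies recorded in a truth table; distinct reads
  are guaranteed to differ in (coordinate, barcode), so the dedup removal
  count must match the truth table *exactly*;
* negative-binomial stranded counts with rate-class-dependent sense means
  (10/40/120/400/1200), low antisense means (median 5), a common
  dispersion, ~10% log-normal library-size jitter, and planted DE sets.

Not emulated (deliberately): sequencing errors, base composition and
mappability, PCR bias beyond exact duplicates, splice structure, and any
real genome sequence.  A green recovery test therefore establishes that the
*computational* pipeline inverts its own generative model at the stated
tolerances — not that it is robust to artefacts real libraries contain.

## Numerical notes and limitations

* Extension pile-up is exact integer arithmetic (diff/cumsum); the
  brute-force oracle comparison is bit-exact.
* `group_rm_anova` returns p = 1 when all differences are exactly zero and
  floors p at the smallest positive double when the difference is constant
  and nonzero.
* Hypergeometric and Poisson tails come from R's `phyper`/`ppois`;
  enumeration oracles in the tests agree to 1e-12/1e-10.
* k-means recovery (ARI >= 0.9) is only guaranteed for well-separated
  planted clusters (centroid spacing >= 6 sigma); real occupancy maps are a
  continuum and cluster labels there are descriptive, not inferential.
* The NB test's calibration was tuned for the generator's common-dispersion
  world; with strongly heterogeneous dispersions, `prior_df = 50`
  overshrinks and per-gene dispersion methods (DESeq2, edgeR) should be
  preferred on real data.
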