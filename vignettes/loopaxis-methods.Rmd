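---
title: "Methods: interval statistics, signal numerics and DSB interference in loopaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval statistics, signal numerics and DSB interference in loopaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

loopaxis packages the computational core of a meiotic double-strand-break
(DSB) ChIP study: where does a DSB-sensing kinase sit on meiotic
chromosomes relative to DSB hotspots and the Red1/Hop1/Rec8 chromosome
axis, and how strongly do coincident DSBs at neighbouring hotspots
interfere with each other? This vignette records the models, parameter
choices and numerical conventions behind each module, and what the
synthetic test bed does and does not establish about real data.

## Coordinate and container conventions

All on-disk formats are BED-family (0-based, half-open, tab-separated);
in memory, features are `GRanges` (1-based closed, the Bioconductor
convention) and genome layouts are `Seqinfo` objects. The readers and
writers convert at the boundary, and the constructor `features()` accepts
0-based half-open coordinates directly so that code and files agree.
Strand is ignored throughout: hotspots, axis sites and coverage peaks are
unstranded objects. A feature "midpoint" is `floor((start0 + end0) / 2)`,
which is deterministic for even-length intervals.

Internally the interval algebra decomposes `GRanges` into per-chromosome
`IRanges` and reassembles once per operation. This is purely a
performance measure (whole-`GRanges` set operations carry a large
per-call constant) and is invisible in the results; the per-base oracle
suite in `tests/` pins the semantics.

## Interval algebra and the axis definition

* `merge_intervals(fs, max_gap)` merges intervals whose separation is
  strictly less than `max_gap` (the "regions closer than 350 bp are
  merged" rule); `max_gap = 0` still unions overlapping and book-ended
  intervals, which makes it the per-base union.
* `subtract_features(a, b)` is a per-base difference that splits
  intervals and lets fragments inherit their parent's score, while the
  `t0` stage of the consolidation cascade removes whole peaks. These are
  deliberately two different behaviours: control-peak lists are described
  as *subtracted from the peak list* (list-level removal) while
  hyper-ChIPable regions are *removed from the overlapping peak
  coordinates* (base-level trimming).
* `consensus_features(sets, k)` defines axis sites as the maximal regions
  where at least `k` of the `n` marks cover a base (used with
  Red1/Hop1/Rec8 and `k = 2`). The phrase "sites that overlap at least
  two of the three marks" is genuinely ambiguous between this per-base
  vote and whole-site retention; both are implemented (`mode = "base"`,
  the default, and `mode = "site"`), and the per-base mode is canonical
  because it yields coordinates supported by two independent marks at
  every base.

## The shuffle null and its calibration

`shuffle_features()` relocates every interval uniformly at random by
rejection sampling (up to 10,000 attempts per interval, then an error
naming the chromosome), conserving the length multiset, optionally
per-chromosome, with no overlap among placed intervals nor with a
`forbidden` set — the behaviour of constrained `shuffleBed`.
`overlap_significance()` reports:

* an empirical permutation p with the +1 correction,
  `p = (1 + #{shuffled count >= real}) / (n_shuffles + 1)`, so p is never
  0 with the small shuffle counts (10) typical of this design;
* a two-sided rank-sum p comparing per-interval overlap indicators of the
  real set against the pooled shuffles (mid-ranks, normal approximation,
  continuity correction, via `wilcox.test`). The underlying two-sample
  contrast is stated loosely in the source analyses (a single real count
  cannot form a two-sample test), so both statistics are reported and
  neither is privileged.

With 10 shuffles the empirical p lives on the 11 atoms k/11. Tied
shuffle counts push it upward, so it is *conservative*: P(p &le; k/11)
&le; k/11, and the smallest achievable level (1/11 &approx; 0.091) is
above 0.05. Calibration is therefore tested on the randomized-rank
probability integral transform of the real count among the shuffle
counts, which is exactly uniform under the null, alongside one-sided
validity checks of the discrete p at its atoms. A KS test of the raw
discrete p against a continuous uniform would reject for structural
reasons at any reasonable sample size and would say nothing about the
test's validity.

## Peak consolidation cascade

`consolidate_peaks()` chains: smallest-member reduction of overlap
components across replicate-by-cutoff peak calls, a `< 350` bp gap merge,
whole-peak removal of pre-meiotic (t = 0 h) peaks, base-level blacklist
trimming, and a strict `> 200` bp length filter. Two open readings are
settled as follows: "only the smaller region from overlapping peaks" is
applied per overlap-connected component (not pairwise-iteratively), with
ties broken leftmost then by input order, because component semantics are
order-independent and deterministic; and the gap merge precedes t0
removal, following the order in which the processing is described
(`merge_before_t0 = FALSE` swaps them). The cascade is idempotent when
re-run on its own output with the same controls.

## Signal tracks

`binned_track` stores one numeric vector per chromosome at a fixed bin
size; `NA` marks missing data, distinct from 0. bedGraph rasterisation
uses length-weighted means with uncovered bases read as 0 (coverage
semantics); derived tracks may carry `NA` where analysis drops data.
`normalize_rpkm()` is `value * 1e9 / (library_size * bin_size)`.
Background correction subtracts each control track from each replicate
and then averages replicates; a `floor_at_zero` flag exists but is off by
default because negative residuals carry information about control noise.

`hann_smooth()` convolves with the normalised Hann taper
`w_j = 0.5 (1 - cos(2*pi*j/(M-1)))`, `M` = window/bin rounded to the
nearest odd count of bins; at chromosome edges the kernel is truncated
and renormalised (zero-padding would bias telomere-proximal signal
downward). The kernel sums to one, so interior signal mass is conserved.

Pile-ups (`pileup_profile`) sample fixed offset bins around feature
midpoints and average across features; offset bins outside a chromosome
are excluded from that offset's mean rather than zero-filled, again to
avoid edge attenuation. Per-feature averaging (not read pooling) is used;
a heatmap matrix (`profile_matrix`) shares the bins and orders rows by a
score such as DSB strength. `window_signal` quantifies fixed windows
(600 bp on hotspots, 2 kb on axis midpoints, 1.5 kb in the low-coverage
setting) and can drop windows overlapping an exclusion set by at least
10% of their width — the literal complement of keeping windows that
overlap the axis by less than 10%. Percentile partitions are rank-based
equal-count bins (stable ties), matching equal-population decile
boxplots, with the top 20% being indices 8 and 9 of 10.
`window_correlation` averages both tracks in 100-bp windows and reports
Pearson r, Spearman rho and R² = r² of the simple least-squares fit (the
identity the source analyses use).

## ChIP-qPCR and DSB interference

`percent_ip` is `100 * q_ip / (q_input * 20 * 10)` by default: the input
is diluted 20-fold before qPCR and represents a 10-fold smaller volume
than the IP aliquot. The interference pipeline quantifies, from Southern
band fractions:

* `observed_dc`: the central-probe double-cut fraction times the probe
  multiplicity m (3 for a probe hybridising to three parental loci);
* `expected_dc`: the independence product `f1 * (f2_raw + dc_obs)`. The
  loss correction adds observed double cuts back to the distal (site-II)
  band because a doubly cut chromatid runs as the short double-cut
  fragment and is physically absent from that band. The mid-range
  (PFGE) assay computes the plain product of directly measured single-cut
  frequencies (`correct_loss = FALSE`);
* `interference_value`: `I = 1 - dc_obs / dc_exp`. Positive I means
  interference, zero independence, negative concerted cutting. The two
  formula variants printed in the source (`1 - obs/exp` vs `1 - exp/obs`)
  disagree; the first is adopted because only it produces negative values
  when double cuts exceed expectation, which is how the sign language is
  used throughout.

`interference_from_cohort` attaches a delta-method standard error by
propagating the multinomial covariance of the four outcome counts
through a numerically differentiated statistic. Simulation shows the
corrected estimator is unbiased as n grows while the uncorrected one
converges to about −0.10 at p1 = p2 = 0.1 and I = 0 — a spurious
"concerted cutting" signal that illustrates why the loss correction is
applied.

## The synthetic generator

`sim_config()` defaults are the study conditions, fixed once:

* genome: 16 chromosomes, ~12.07 Mb (approximate real lengths);
* 3,000 hotspots of 190 bp, disjoint from axis sites, with midpoints at
  least 1.2 kb apart (hotspots occupy distinct nucleosome-depleted
  promoters; the spacing also keeps 600-bp quantification windows from
  bleeding into neighbours);
* per-cell cleavage strengths log-normal (`meanlog = log(0.005)`,
  `sdlog = 1.2`) clipped at 0.15 — several orders of magnitude of
  dynamic range with the strongest hotspots cut in ~15% of cells. The
  parametric form is a modelling choice (no published form exists) and
  is exposed in the config;
* axis sites every ~15 kb (±2 kb jitter), 500 bp wide — ~800 sites
  genome-wide;
* coverage: background 0.5 reads/bp in 20-bp bins; the DSB sensor
  ("tel1") places two Gaussians (σ = 150 bp) at ±300 bp around each
  hotspot midpoint, scaled by strength (12,000 expected reads per unit
  strength, i.e. a strong hotspot rises ~4–5× over background, the
  regime in which discrete peaks are visible), plus a weak axis kernel;
  the catalyst ("spo11") places one narrow Gaussian (σ = 100 bp) at the
  midpoint plus a stronger axis kernel (250 reads/site vs 80),
  reflecting its DSB-independent assembly on the axis. Counts are
  Poisson per bin — the pipeline consumes coverage, never reads.

The double-cut cohort model is the minimal one consistent with the
interference definition: `P(DC) = (1 - I) * p1 * p2`, marginals
preserved, no distance kernel (the assay is two-site). The measurement
model makes the loss correction exact by construction (double cuts vanish
from band II), because the band geometry behind the correction is
asserted, not derived, in the source; a flag disables it. A symmetric
correction for the site-I band is deliberately *not* applied, matching
the published procedure.

What passing tests show — and do not. The generator reproduces the
qualitative structure of the study's data (bimodal sensor vs unimodal
catalyst, axis-dominant catalyst, hotspot–axis depletion, recoverable
interference) under idealised Gaussian kernels, flat background and
Poisson noise. Real ChIP data add mappability artefacts, copy-number and
GC biases, fragment-length smearing and hyper-ChIPable loci that the
generator represents only via the explicit blacklist inputs; passing the
recovery tests validates the estimators' logic, not robustness to those
artefacts.

## Problem sizes and numerical choices

Test and acceptance runs use the full default landscape (12 Mb, 3,000
hotspots) for profile and recovery checks; the shuffle-null calibration
uses 500 independent tests of 30 intervals against 40 on a 100-kb
chromosome; interference recovery uses 10⁵ cells per grid point (10⁶ for
the bias demonstration, where the asymptotic bias must dominate its
standard error); the interval-algebra oracle runs 60 random landscapes
by 4 operations on a 10-kb chromosome. Empirical p-values use the +1
correction; rank-sum tests use the normal approximation (the indicator
data are heavily tied, so exact enumeration is unavailable anyway);
Hann kernels of even bin count round to the nearest odd; percentile ties
resolve by first occurrence. Generator seeds derive deterministic
sub-seeds per stage so that one user seed reproduces every artefact
byte-for-byte.
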