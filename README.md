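# loopaxis

Analysis toolkit for meiotic double-strand-break (DSB) ChIP experiments
in budding yeast, where programmed Spo11 DSBs form at ~190-bp hotspots in
chromatin loops that are tethered to the Red1/Hop1/Rec8 chromosome axis.
The package is written for researchers asking where a DSB-responsive
protein (e.g. the Tel1/ATM kinase) binds relative to hotspots and axis
sites, and how strongly coincident DSBs at neighbouring hotspots
interfere.

It provides, as plain R functions over `GRanges`/`Seqinfo` containers:

* **Interval statistics** — BED/narrowPeak I/O, merge/intersect/subtract
  algebra, k-of-n consensus (the axis definition: bases covered by ≥ 2 of
  the 3 axis marks), pairwise overlap tables with "alone" fractions, and
  a constrained-shuffle permutation test of overlap significance
  (length-preserving, per-chromosome, avoiding a forbidden set), with the
  +1-corrected empirical p `(1 + #{shuffled ≥ real})/(n + 1)` and a
  rank-sum p on per-interval overlap indicators.
* **Peak consolidation** — the multi-cutoff cascade for noisy ChIP-seq
  peak calls: smallest-member reduction of overlap components, < 350 bp
  gap merge, whole-peak removal of pre-meiotic (t = 0 h) peaks, trimming
  of hyper-ChIPable blacklist bases, and a strict > 200 bp length filter.
* **Signal-track numerics** — bedGraph rasterisation onto fixed bins,
  RPKM normalisation (`value · 10⁹ / (library · bin)`), background/t0
  subtraction with replicate averaging, Hann-window smoothing
  (`w_j = 0.5(1 − cos(2πj/(M−1)))`, normalised), metagene pile-ups and
  heatmap matrices around feature midpoints, fixed-window quantification
  with axis-overlap exclusion, rank-based percentile partitions, and
  100-bp-window track correlations (Pearson r, Spearman ρ, R² = r²).
* **qPCR and DSB interference** — percent input
  `%IP = 100 · q_IP / (q_input · 20 · 10)`; and the interference
  statistic `I = 1 − DC_obs / DC_exp`, with the central-probe
  multiplicity correction (`DC_obs = m · DC_raw`, m = 3) and the
  double-cut loss correction (`DC_exp = f₁ · (f₂ + DC_obs)`, because
  doubly cut molecules vanish from the distal single-cut band). Positive
  I = interference, 0 = independence, negative = concerted cutting.
* **A ground-truthed simulator** — hotspot/axis landscapes (~3,000
  hotspots, log-normal strengths capped at 15% per-cell cleavage),
  DSB-dependent bimodal sensor coverage vs unimodal catalyst coverage
  with Poisson noise, per-chromatid double-cut cohorts under a tunable
  interference parameter, and qPCR plates — so the whole pipeline runs
  and is tested without any external download.

## Worked example

```r
library(loopaxis)

## DSB interference from Southern band fractions
interference_from_bands(f1 = 0.20, f2_raw = 0.15, dc_central_raw = 0.02)
#> DSB interference: observed DC 0.06, expected DC 0.042, I = -0.4286
```

The central probe saw 2% of lane signal in double cuts; ×3 probe loci
gives `DC_obs = 0.06`. The loss correction restores site II's frequency
to `0.15 + 0.06 = 0.21`, so `DC_exp = 0.20 × 0.21 = 0.042`, and
`I = 1 − 0.06/0.042 = −0.43`: double cuts occur more often than
independence predicts — concerted cutting, the signature seen when the
Tel1-dependent interference pathway is broken.

```r
## synthetic landscape -> coverage -> profile shape and strength recovery
cfg <- sim_config(seed = 1,
                  genome = genome_layout(c("chrA", "chrB"), c(5e5, 3e5)),
                  n_hotspots = 180, axis_spacing = 15000)
fx <- simulate_features(cfg)
tr <- simulate_chip_tracks(cfg, fx$hotspots, fx$axis)
sc <- S4Vectors::mcols(fx$hotspots)$score
top <- fx$hotspots[partition_by_percentile(sc, 10) >= 8]   # top 20%
prof <- pileup_profile(hann_smooth(tr$tel1, 100), top)
# -> profile maxima at -270 bp and +290 bp: the bimodal, DSB-end-flanking
#    signature of the sensor kinase around hotspot midpoints
ws <- window_signal(tr$tel1, fx$hotspots, 600, stat = "summed_count")
cor(ws$value, sc)
#> 0.984   # 600-bp window signal recovers true hotspot strengths

overlap_significance(fx$hotspots, fx$axis, cfg$genome,
                     forbidden = fx$hotspots, n_shuffles = 10, seed = 8)
#> Overlap permutation test: 0/180 real intervals overlap the reference
#>   shuffled counts (n = 10): 11, 9, 7, 12, 10, 11, 5, 10, 11, 13
#>   empirical p: enrichment 1, depletion 0.09091; rank-sum p 0.00125
```

Real hotspots avoid the axis (0 overlaps) while every one of 10 shuffled
hotspot sets overlaps it 5–13 times: DSB hotspots are depleted from axis
regions at the smallest p the 10-shuffle design can produce (1/11).

A thin command-line wrapper is installed at `inst/cli/loopaxis`
(subcommands `simulate`, `consensus`, `shuffle-test`, `consolidate`,
`pileup`, `interference`, `percent-ip`); it only calls the exported
functions above.

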