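# stripequant

Quantitative analysis of anterior–posterior (AP) stripe expression from
per-nucleus point clouds of *Drosophila* blastoderm embryos — the kind of
data produced when embryos are stained by in situ hybridization, imaged at
cellular resolution, and segmented into a table of ~6000 nuclei with 3-D
positions and per-channel fluorescence values.

The package is written for people comparing the expression driven by
enhancer variants (reporter constructs or endogenous edits) and asking two
quantitative questions: *how much* expression does each variant drive, and
*where* are the stripe boundaries? It implements:

* **PointCloud / FASTA / PWM I/O** — a self-describing plain-text embryo
  dialect, plus tidy readers for sequences and position count matrices.
* **Co-stain normalization with QC** — reporter levels are divided by the
  95% quantile of *hkb* expression in the posterior 10% of each embryo;
  within each stain × genotype group, embryos are regressed
  (q99 reporter ~ q95 co-stain) and influential outliers flagged by
  Cook's distance (default threshold 4/n). Levels are only ever compared
  within one staining batch.
* **AP trace extraction** — mean expression in 16 dorsoventral strips ×
  100 AP bins; lateral strips averaged; minimum along the axis subtracted
  as background.
* **Stripe metrics** — windowed peak levels; stripe boundaries as
  inflection points (extremal first difference of a 3-bin-smoothed trace,
  parabolic sub-bin refinement); boundary shifts in cell widths
  (1 cell ≈ 1% egg length); seven-stripe segmentation with stripe-1
  internal normalization.
* **Statistics** — per-stain peak ratios with one-sample t-tests against
  1; Welch tests between fold changes; per-DV-position Mann-Whitney U
  boundary tests with Bonferroni correction; rank-sum stripe-level tests.
* **Motif scanning** — PATSER-style PWM scanning with exact tail p-values
  (dynamic-programming score distribution), consensus sites supported by
  several PWMs at once, and scrubbing of high-affinity sites from spacer
  sequences.
* **A synthetic embryo generator** — ellipsoid-surface nuclei, logistic
  stripe profiles with analytically known boundaries, an *hkb*-like
  posterior domain, per-stain staining factors, noise, and outlier
  embryos, so the entire pipeline is testable with known ground truth.

The model at the core of the comparisons: a stripe is
`A · σ((x − a)/k) · σ((p − x)/k)` along AP position `x` (fraction of egg
length), so `a` and `p` are simultaneously the logistic midpoints and the
profile's inflection points; a fold change between genotypes is the mean
over stains of `peak(trace_num) / peak(trace_den)` computed within each
stain, tested against 1.

## Worked example

Simulate a 1.45-fold expression difference between two reporter lines
(5 stains, 10 embryos per genotype per stain, default noise), and run the
whole analysis — QC, normalization, traces, metrics, ratios, tests:

```r
library(stripequant)
res <- run_reporter_analysis(list(
  simulate = list(fold = 1.45, n_stains = 5, n_per_genotype = 10),
  seed = 11))
res$tests
#>   genotype_num genotype_den mean_ratio t_stat df p_value n_stains alternative
#> 1            B            A       1.48   4.89  4  0.0081        5   two.sided
res$metrics
#>   genotype n_embryos peak_level peak_se anterior anterior_se posterior posterior_se
#> 1        A        49      0.908 0.00238    0.351    1.48e-04      0.45     1.56e-04
#> 2        B        47      1.339 0.05601    0.351    9.32e-05      0.45     8.36e-05
```

The recovered mean per-stain ratio (1.48 over 5 stains) estimates the
simulated fold of 1.45 and is significantly different from 1
(p = 0.0081); both genotypes' anterior boundaries sit at 0.351 egg
length, matching the generating value 0.35 to within a tenth of a cell
width. `autoplot()` methods draw the trace with its SEM ribbon and the
per-stain ratio plot; `tidy()`/`glance()` return the tables above as
tibbles.

Binding-site discovery on the bundled synthetic enhancer (a 484-bp
minimal fragment inside a 798-bp extended one, with a common Gt-like site
planted in the downstream flank):

```r
fa <- read_fasta(system.file("extdata", "synthetic_enhancers.fa",
                             package = "stripequant"))
pwms <- lapply(list.files(system.file("extdata", package = "stripequant"),
                          "[.]pwm$", full.names = TRUE), read_pwm)
hits <- lapply(pwms, function(p)
  scan_pwm(fa$sequence[fa$name == "extWT_synthetic"], p, p_threshold = 0.001))
consensus_sites(hits)
#>   start end width n_pwms
#> 1   634 644    10      3
```

All three matrices agree on exactly one interval — the planted site,
downstream of the minimal fragment (which ends at position 534).

## Layout

* `R/` — implementation; one file per stage (I/O, embryo container,
  generator, normalization, traces, metrics, statistics, PWM machinery,
  pipelines, tidiers, plots).
* `vignettes/stripequant-methods.Rmd` — the methods vignette: model,
  conventions, estimator choices, calibration, limitations.
* `inst/extdata/` — small synthetic fixtures (sequences, PWMs); all
  labelled synthetic.
* `inst/scripts/run_pipeline.R` — thin command-line wrapper over the two
  pipeline entry points.
* `tests/testthat/` — unit, property and acceptance tests with
  brute-force oracles in `helper-oracles.R`.
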