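# damfretr

Quantitative analysis of DAmFRET (distributed amphifluoric FRET) flow
cytometry — the single-cell assay that asks whether a protein's
self-assembly is *continuous* with concentration, or *discontinuous*:
rate-limited by a stochastic nucleation event that lets cells hold the
protein supersaturated. The package is aimed at researchers analyzing
concentration-dependent protein phase behavior in cytometry data
(innate-immune signalosome domains, prion-like domains, and similar
systems), and at anyone who needs the assay's statistical machinery in a
reproducible, tested form.

## What it computes

For each well of per-cell events (FSC/SSC, donor, autofluorescence,
acceptor, FRET):

* **Gating and QC** — scatter/singlet/expression gates (logicle transform
  implemented from the biexponential definition), AmFRET = FRET/acceptor,
  well exclusion below 2500 events or 3.5 p.d.u. mean acceptor, 25%
  instance-retention filtering.
* **Profile** — the 64-bin logarithmic expression histogram; per-bin
  99th-percentile FRET-positive gate from a monomer control; fraction
  assembled per bin and overall (`fgate`).
* **Continuity** — bootstrapped, density-filtered median-AmFRET spline
  (Scott's-rule bins; 20 cells / density 500 / 25%-outlier eligibility;
  zero-phase Butterworth denoising; 100 bootstraps); transition point and
  range from the spline derivatives; Hartigan's dip test of unimodality
  inside the transition range (compiled implementation, Monte-Carlo
  p-values); class = discontinuous iff p < 0.05, with low / high /
  low-to-high subtyping of continuous profiles and majority voting across
  replicates.
* **C50 and supersaturability** — bounded least-squares fit of the
  stretched exponential

  AmFRET(c) = Amp·(1 − exp(−ln2·(c/C50)^a)),

  which reaches Amp/2 exactly at c = C50; automated fit-window selection;
  Monte-Carlo parameter errors; supersaturability as the same-batch fold
  reduction C50_stochastic / C50_seeded.
* **Seedability screen** — per-batch standardization of log10 C50 and
  fgate, directional per-protein IQR outlier degrees, seedability = their
  mean, hits at mean + 3 SD of all scores, negative-control diagnostics,
  and replicate consistency with Wald intervals.
* **Morphology** — rolling-ball background subtraction, intermeans
  ("Default") thresholding, 8-connected components, per-object CV and
  ellipse aspect ratio, and the printed CV/AR classification rules for
  diffuse / punctate / fibrillar assemblies.
* **Network statistics** — score-filtered interaction graphs, degree and
  betweenness centralities, Mann–Whitney, chi-square with Cramér's V,
  Spearman, binomial intervals, log-log power-law fits, Ward clustering of
  seedability matrices.
* **Synthetic data** — generators for event tables, full screens, and
  images with known ground truth (`simulate_events()`,
  `simulate_screen()`, `render_objects()`), which the test suite uses to
  validate every stage end to end.

## Worked example

```r
library(damfretr)

# a discontinuous well and a monomer control, 100k cells each
ctrl <- simulate_events(phenotype_spec("one_state_low"), 1e5, rng_seed = 1)
well <- simulate_events(phenotype_spec("discontinuous", true_c50 = 200,
                                       true_amp = 0.35), 1e5, rng_seed = 2)
ctrl <- compute_amfret(apply_gates(ctrl))
well <- compute_amfret(apply_gates(well))

gate <- fret_positive_gate(bin_events(ctrl))
fa <- fraction_assembled(bin_events(well), gate)
cl <- classify_well(well, rng_seed = 2)
fit <- fit_weibull(mean_curve(bin_events(well)))

round(fa$fgate, 3)
#> [1] 0.621
cl$class
#> [1] "discontinuous"
round(cl$dip$p_value, 4)
#> [1] 5e-04
round(fit$C50, 1)
#> [1] 202.8
```

Here `fgate = 0.621` says 62% of cells sit above the control-derived
FRET gate; the dip test rejects unimodality inside the detected transition
range (p = 0.0005, the smallest value 2000 null samples can resolve), so
the well is called discontinuous — it has a nucleation barrier — and the
stretched-exponential fit puts its half-maximal assembly concentration at
~203 p.d.u., recovering the planted value of 200.

The numbered scripts under `analysis/` run the full workflow on synthetic
data (simulate wells → classify continuity → fit C50/supersaturability →
screen hit-calling and replicate consistency → morphology → network
statistics), writing tables under `results/`. The methods vignette
(`vignettes/damfret-methods.Rmd`) documents the models, defaults and
numerical conventions.

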