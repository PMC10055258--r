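---
title: "Detecting nucleation barriers in DAmFRET data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nucleation barriers in DAmFRET data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and the question

DAmFRET (distributed amphifluoric FRET) measures, cell by cell, how a
protein's self-assembly depends on its concentration. Each cell expresses
the protein fused to the photoconvertible fluorophore mEos3; partial
photoconversion creates donor and acceptor populations in a fixed ratio, so
the FRET signal normalized by acceptor intensity (**AmFRET = FRET
intensity / acceptor intensity**) reports self-association, while acceptor
intensity itself is the per-cell expression proxy. Plotting AmFRET against
expression over tens of thousands of cells spanning several decades of
expression yields a two-dimensional profile whose *shape* distinguishes two
physical regimes:

* **continuous** assembly: AmFRET rises smoothly with concentration — every
  cell equilibrates, so at each concentration the AmFRET distribution is
  unimodal;
* **discontinuous** assembly: over a window of concentrations, genetically
  identical cells split into an unassembled low-AmFRET population and an
  assembled high-AmFRET population. Bimodality at a *fixed* concentration
  means assembly is rate-limited by a stochastic nucleation event — the
  signature of a nucleation barrier, which allows cells to hold a protein
  supersaturated.

`damfretr` implements the quantitative machinery around that readout: event
gating, the 64-bin AmFRET profile and `fgate`, the continuity classifier,
saturation-concentration (C50) estimation by stretched-exponential fitting,
hit calling for an all-by-all seeding screen, image-based morphology
classification, and the downstream network statistics. A synthetic-data
module generates event tables, screens, and images with known ground truth
so that every stage is testable without instrument data.

# Gating and the event schema

Events carry forward/side scatter, donor, autofluorescence, acceptor and
FRET channels (instrument aliases FS00.A/H/W, SS02.A, FL03.A, FL17.A are
mapped onto the schema by `read_well_csv()`). Gating follows the standard
scheme — scatter (debris), FSC-H vs FSC-W (singlets), donor vs
autofluorescence (expressing cells) — with rectangular thresholds by
default and optional polygons. Gates *flag* rows; nothing is deleted, and
gating is idempotent.

For display-geometry gating the package implements the logicle transform
from its biexponential definition with Newton inversion
(`logicle_params()`, `logicle_transform()`), plus an asinh fallback. The
transform parameters (T, M, W, A) are exposed because no universal values
exist; AmFRET itself is always computed on untransformed intensities, since
it is a physical ratio.

Well-level QC excludes wells with fewer than 2500 gated events or mean
acceptor intensity below 3.5 p.d.u. (boundaries inclusive: the failing
conditions are "fewer than" / "less than"). Proteins or seeds retaining
less than 25% of their wells after QC are dropped entirely
(`instance_retention_filter()`).

# The 64-bin profile and fgate

Expression is divided into 64 logarithmically spaced bins over a fixed
global range, default $(10^{0.5}, 10^{4.5})$ p.d.u. — wide enough to
accommodate all simulated data sets; bins are left-closed with the top bin
closed. A monomer-only control defines, per bin, the 99th percentile of its
AmFRET distribution; sample cells above that per-bin gate are counted as
assembled. The per-bin assembled fraction and the gross fraction `fgate`
follow. By construction the control's own `fgate` is about 0.01, a property
the test suite checks. Bins where the control is too sparse (default < 20
cells) inherit the nearest populated bin's gate — a deliberate,
assumption-free fallback.

# Continuity classification

The classifier asks whether AmFRET is bimodal *within the transition
region*, located as follows:

1. **Binning**: log-expression bins from Scott's rule
   (width $3.49\,\sigma n^{-1/3}$).
2. **Eligibility**: a bin enters the fit only with at least 20 cells,
   density (count / AmFRET IQR) at least 500, and at most 25% outliers.
   "Outlier" is defined by Tukey fences (1.5 IQR beyond the quartiles) —
   the standard parameter-free choice.
3. **Spline**: per-bin median AmFRET, denoised with a zero-phase
   second-order Butterworth low-pass filter (normalized cutoff 0.2 —
   mild smoothing that preserves step edges) and interpolated cubically
   onto a 256-point grid. The whole construction is bootstrapped 100 times
   by resampling cells with replacement; the reported spline is the
   replicate mean. The bootstrap is drawn as multinomial bin counts plus
   within-bin resampling, which has exactly the law of resampling cells.
4. **Transition metrics**: per replicate, the transition point is the
   maximum of the first finite-difference derivative; the start and end are
   the maximum (minimum) of the second derivative before (after) it.
   Argmax ties break leftmost. Medians across replicates are reported.
   A flat spline (maximum slope below $10^{-4}$) is flagged degenerate and
   the window widens to the full grid.
5. **Dip test**: Hartigan's dip statistic of the AmFRET values of cells
   inside the transition window, with a Monte-Carlo p-value from 2000
   uniform null samples of the same size. p < 0.05 calls the profile
   discontinuous; p ≥ 0.05 (including equality, per the wording of the
   rule) calls it continuous.

Continuous profiles are subtyped against a monomer-reference AmFRET level
(default 0.1): minimum and ending spline values both below the reference =
"low", both above = "high", minimum below and end above = "low_to_high".
The fourth combination is reported as "anomalous" rather than forced into a
class. Replicate wells are combined by majority vote; ties are
"unresolved" for manual review.

## The dip statistic

The dip — the minimum over all unimodal distribution functions of the
sup-distance to the empirical CDF — is implemented in compiled code from
its greatest-convex-minorant / least-concave-majorant characterization
(`src/dip.cpp`). Because the computation is easy to get subtly wrong, the
test suite validates it against an *exact* independent oracle: for small
samples, the minimax fit over every modal structure (mode inside each gap,
kink at each point, atom at each point) is solved as a family of linear
programs, and the two must agree to $10^{-6}$. Hand-derivable cases
(equally spaced points give $1/(2n)$; two balanced point-pairs give 0.25)
and the bounds $1/(2n) \le \mathrm{dip} \le 1/4$ are asserted as well.

Windows larger than 10,000 cells are subsampled (deterministically under
the seed) before testing. The cap matters for power, not just speed: the
dip statistic of a fixed mixture is essentially independent of $n$ while
the null critical value shrinks like $1/\sqrt n$, so lopsided mixtures
(e.g. 8% in the minor mode, common when the detected window includes the
high plateau) need $n \gtrsim 5000$ to reject. Monte-Carlo null tables are
cached per sample size within a session.

# C50 and supersaturability

The mean AmFRET per bin (bins with ≥ 100 cells) is fit to the stretched
exponential

$$\mathrm{AmFRET}(c) = Amp\,\bigl(1 - e^{-\ln 2\, (c/C_{50})^{a}}\bigr),$$

whose value at $c = C_{50}$ is exactly $Amp/2$ for every steepness $a$.
Initial guesses come from a Gaussian-smoothed curve (sigma 2 bins): $Amp$ =
smoothed maximum, $C_{50}$ = concentration at half that maximum, $a = 2$.
$Amp$ and $C_{50}$ are constrained to within 2-fold of their guesses and
$a$ to $[0.1, 10]$; fitting is bounded nonlinear least squares
(Levenberg–Marquardt, ftol $10^{-8}$ or better). A fit whose $Amp$ or
$C_{50}$ lands on the 2-fold box is reported `converged = FALSE`; the $a$
bounds are hard constraints that may legitimately bind for step-like seeded
curves and do not invalidate a fit.

The window over which the curve is fit replaces a manual
choose-by-inspection step with a deterministic rule: the window starts
where the smoothed slope first exceeds 5% of its maximum for two
consecutive bins and ends where it falls back below; a manual override is
available and logged. Parameter errors come from a residual-parametric
Monte Carlo (100 refits of the fitted curve plus Gaussian noise at the
residual SD) — the underlying published procedure is not specified in
detail, so the package uses this standard scheme and documents it.

Supersaturability is the fold reduction
$C_{50}^{\mathrm{stochastic}} / C_{50}^{\mathrm{seeded}}$, computed only
within an experimental batch (cross-batch ratios are an error). Both
orientations are returned explicitly because prose descriptions of such
ratios are easy to read in either direction.

# The seedability screen

Per well the pipeline records the Weibull $C_{50}$ and `fgate`. Hit calling
then proceeds: take $\log_{10} C_{50}$; standardize both variables within
each experimental batch to mean 0, variance 1 (sample SD by default,
configurable); within each query protein compute directional outlier
degrees across all of its seeds — how many IQRs the standardized
$\log_{10} C_{50}$ lies *below* the protein's median, and `fgate` *above*
it, clipped at zero; average the two degrees into the **seedability**
score; call hits at or above mean + 3 SD of all seedability values. Two
negative-control seeds per protein are included in every per-protein
median/IQR — they anchor the null — and a diagnostic confirms that their
seedability partitions away from hits. Replicate screens are compared by
hit-call consistency with a Wald binomial interval (chosen because it
reproduces the printed-style intervals exactly; Wilson is available), and
by the Pearson correlation of seedability with and without double-negative
pairs.

# Morphology

From each z-stack the brightest plane is taken (ties to the lower index).
Background is removed by a rolling-ball subtraction implemented as
grayscale opening with a disc structuring element — the flat limit of a
wide, shallow ball: structures narrower than the ball survive, smooth
gradients do not. The default radius is 100 px as in high-content
acquisitions; synthetic fixtures use radius 14 against their smaller
objects. Thresholding uses the iterative intermeans (isodata) criterion on
a 256-bin histogram; because multimodal histograms can admit several
intermeans fixed points, the package solves the criterion exhaustively and
takes the smallest — the background/foreground split, which is what the
classical method finds on fluorescence images. Objects are 8-connected
components; per object the mean, SD, CV = SD/mean·100, and the aspect
ratio from the best-fit ellipse (square root of the second-central-moment
eigenvalue ratio, with the 1/12 pixel-extent correction so a uniform
rectangle's AR is exact) are measured. Classification applies the printed
CV/AR cutoff sets verbatim (set 1: CV 55, AR 1.159/1.16; set 2: CV 17/18,
AR 1.4/1.41). Combinations the printed rules leave uncovered — e.g. low CV
with high AR, or the razor-thin boundary gaps — return "unclassified"
rather than a silent assignment, mirroring how ambiguous wells were
re-checked manually in practice.

# Network and correlation statistics

`build_network()` keeps physical-interaction edges with confidence ≥ 900
(inclusive), deduplicates to the maximum score, and labels a multi-domain
protein discontinuous if *any* of its domains is. Degree centrality is
degree/(n−1); betweenness is computed by shortest-path accumulation and
reported both raw and normalized, since published analyses rarely state the
normalization. The statistical helpers wrap the standard tests
(Mann–Whitney U with midranks and exact small-sample p-values, Pearson
chi-square without Yates correction — the printed $X^2$/V pairs are
self-consistent only without it — Spearman with exact permutation p at
small n, Wald/Wilson binomial intervals, OLS power-law fits in log-log
space with confidence bands) and are verified against brute-force
enumeration oracles in the tests. Seedability matrices are clustered with
Ward linkage on log-scaled values, zeros replaced by one tenth of the
smallest positive value.

# What the synthetic data does and does not emulate

`simulate_events()` draws log-normal expression spanning more than three
decades (log10 mean 2.5, SD 0.8 on a 4-decade axis), fills scatter and
donor channels so ≥ 90% of events pass default gates, and generates AmFRET
by behavior: baseline noise (one-state low), the stretched exponential mean
(continuous), or a Bernoulli assembled/unassembled mixture whose
probability is log-logistic in concentration, rising over a configurable
window (0.5 decades by default) — the minimal two-parameter model that
produces the required bimodal transition. Seeding collapses the window:
every cell above $C_{50}/\mathrm{fold}$ is assembled. Measurement noise is
Gaussian in AmFRET (SD 0.05), the simplest model consistent with the
marginal distributions of real profiles. Screens add per-batch
multiplicative expression shifts (log10 SD 0.05) and per-well biological
jitter of the transition concentration (log10 SD 0.05), which is what makes
per-protein IQRs realistic rather than degenerate; screen-protein C50s are
drawn in $10^{2.4}$–$10^{2.9}$ so that both the unseeded transition and the
4-fold-reduced seeded transition stay inside the data-rich expression
range. Rendered images place diffuse plateaus, bright-cored puncta and
anisotropic ridges on a noisy background with margins that prevent overlap.

The generator does **not** emulate FRET photophysics, photoconversion
kinetics, spectral compensation artifacts, autofluorescence correlations,
doublet/debris structure beyond simple planted clusters, or cell-cycle
expression covariation. Passing tests therefore demonstrate that the
*analysis machinery* is correct and well calibrated on data with the
stated statistical structure — not that the assay's instrument-level
artifacts are handled.

# Problem sizes, determinism and numerics

The study-scale assay collects roughly $5\times10^5$ events per well; the
package's simulated wells default to $10^5$ events for single-well analyses
(binomial noise on per-bin fractions is already below the assay's
biological variability at that size) and $10^4$ or fewer for the
12,660-well-scale screen emulation, whose statistics depend on per-well
summaries rather than event counts. The acceptance checks classify 100
wells of $10^5$ cells, run 100 independent 10×12 screens, and draw 2000
Monte-Carlo null samples per dip p-value. Every random step takes an
explicit seed: generators are bit-reproducible, dip subsampling and null
tables are seeded, and the pipeline summary is byte-identical across runs
with the same configuration.

Numerical conventions worth knowing: argmax ties break leftmost
everywhere; quantiles are R type-7; the 3-SD hit threshold uses the sample
SD (configurable); empty profile bins yield NA fractions and are excluded
from `fgate`'s numerator and denominator; the logicle inverse is solved to
$10^{-10}$ on the scale axis; `filtfilt` denoising is skipped for fewer
than 8 bins, where zero-phase edge padding is undefined.

# Known limitations

* The transition-range estimate from the bootstrapped spline tends to run
  long on the high side for strongly assembled wells; the dip test absorbs
  this because the window then contains both modes, but the reported
  `transition_end` should not be over-interpreted.
* The dip p-value is Monte-Carlo, so classifications within ~0.005 of the
  0.05 boundary can flip between seeds; the replicate-majority rule is the
  intended remedy.
* `fit_weibull()` reports honest failure (`converged = FALSE`) for curves
  whose plateau is not observed; downstream screen code drops such wells
  rather than imputing a C50.
* The rolling-ball implementation is O(radius²) per pixel and intended for
  the package's image sizes; very large frames with radius 100 will be
  slow, though correct.
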