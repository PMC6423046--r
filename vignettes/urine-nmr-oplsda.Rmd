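---
title: "Methods: urine 1H-NMR screening with OPLS-DA"
author: "urinmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urine 1H-NMR screening with OPLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urinmr)
```

# The problem

Colorectal neoplasia (CRN: advanced adenoma plus colorectal cancer) is
largely preventable when precancerous lesions are found early, but the
non-invasive screening options are weak: fecal occult-blood testing has
poor sensitivity for precancerous lesions and serum tumor markers (CEA,
CA 19-9) detect only a few percent of cases. Urine 1H-NMR metabolomics
offers a non-invasive alternative: a urine spectrum is a superposition of
hundreds of metabolite signals, and a handful of them (taurine, alanine,
3-aminoisobutyrate up in CRN; ascorbate, citrate, creatinine, glycerol,
hippurate, threonine down) shift systematically in neoplasia.

`urinmr` implements the full analysis chain for this design — simulate or
load spectra, preprocess, fit and validate an OPLS-DA class model,
identify discriminating signals, and express the result as the
diagnostic-accuracy panel a clinician reads (sensitivity, specificity,
PPV, NPV, likelihood ratios).

# The model

## Preprocessing

Each spectrum is divided by the trapezoidal integral of the TSP reference
window (0.00 ± 0.05 ppm). TSP is added to every sample at a fixed
concentration, so this removes the dominant nuisance in urine — overall
dilution — while metabolite-to-metabolite structure is untouched. The
integral rather than the peak height is used because it is robust to the
sampling of the line shape; the window is configurable.

Normalized spectra are binned to 0.0092-ppm buckets. Bins are laid down
from the top of the axis toward the bottom as half-open intervals
`[left, right)`; the topmost axis point belongs to the first bin and a
trailing partial bin at the bottom of the axis is kept. Because no
convention for the grid origin is universal, anchoring at the configured
axis maximum makes the layout deterministic and axis-independent. Bin
values are sums (not means) of point intensities, which preserves
integral proportionality; any bin that overlaps the open residual-water
window 4.6–5.2 ppm at all is dropped whole rather than truncated —
conservative removal of the one region where intensities reflect water
suppression rather than biology.

Columns are then mean-centered and Pareto-scaled:
$x_{ij} \mapsto (x_{ij} - \bar x_j)/\sqrt{s_j}$, with $s_j$ the sample
standard deviation (denominator $n-1$, the chemometrics-software
convention, stated explicitly because either denominator is defensible).
Pareto scaling is the standard metabolomics compromise: unit-variance
scaling amplifies noise bins, bare centering lets the largest peaks
dominate. Zero-variance columns are set to zero rather than dropped so
that column bookkeeping survives train/test splits. The scaling
parameters are first-class objects: a blinded sample is always scaled
with the training parameters, never re-estimated.

## OPLS-DA

The class model is single-response orthogonal projections to latent
structures, fitted by NIPALS with sequential orthogonal deflation. With
$y$ the centered 0/1 class vector and $X$ the scaled matrix, each of $K$
orthogonal rounds computes

- $w \propto X^\top y$, normalized to unit length,
- $t = Xw$, $p = X^\top t / t^\top t$,
- $w_o = p - (w^\top p)\,w$, normalized; $t_o = X w_o$,
  $p_o = X^\top t_o / t_o^\top t_o$,
- deflation $X \leftarrow X - t_o p_o^\top$,

and the predictive component ($w$, $t_p = Xw$, $p_p$,
$q = y^\top t_p / t_p^\top t_p$) is taken from the final deflated matrix.
Deflation forces $t_p \perp t_o$ for every stored orthogonal component;
this and the unit norms are validity invariants of the fitted object and
are re-checked property-style in the tests. The default of $K = 3$
orthogonal components matches the published score-plot construction (one
predictive plus three orthogonal).

Predictions un-center through the stored mean,
$\hat y = q\,t_p + \bar y$, so with 0/1 encoding the a priori cut-off of
0.5 is meaningful; a prediction exactly at the cut-off is classified as
case (a deterministic, documented tie-break). Model quality is reported
as $R^2Y = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$ on training data and
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$ from stratified, seeded
cross-validation; 7 folds by default (the common chemometrics-software
default — the fold count is configurable because no single value is
canonical). When a class has fewer members than the fold count, empty
held-out folds are tolerated; folds are re-drawn (at most 10 times) if a
training part ever loses a class.

Validation mirrors the screening-study design: a stratified per-class
one-third of the samples is blinded, scaling and model are fitted on the
rest, and the blinded samples are scored with the training scaling. The
per-class holdout count is `floor(n / 3)`: for 156 controls and 92 cases
this yields exactly the 52 + 30 blinded / 104 + 62 training partition of
the reference design (rounding to nearest would give 31 cases, which
matches neither class count). The same `floor` rule is applied at any
configurable fraction.

## STOCSY and marker identification

Statistical total correlation spectroscopy correlates a driver variable
with every bin. The driver defaults to the OPLS predictive score $t_p$ —
reading the coefficient coloring of the standard display as correlation
with the predictive component — and any raw bin can be used instead for
classical STOCSY. Covariance (denominator $n-1$, consistent with the
scaling) carries the displayed magnitude and correlation the color;
covariance was chosen over back-scaled loadings because it is
unambiguous, and the loadings remain available from the model object.
Bins with $|r|$ at or above the threshold (default 0.6) are matched to
library signatures within 0.02 ppm of the bin center — roughly two bins
plus line-shape spread — and unmatched hits are reported as
`"unassigned"` rather than dropped.

Because `t_p` is oriented along $X^\top y$ with $y$ encoded 0/1, a
positive correlation means "higher in cases"; `markerDirections()`
aggregates matched bins per metabolite into an increased/decreased call.

Univariate confirmation uses the two-sided Wilcoxon rank-sum test per
metabolite (the source analysis does not name its univariate test; the
rank-sum is the conservative distribution-free choice for skewed urinary
concentrations), with direction read from group medians.

## Quantification, ROC and the accuracy panel

Proprietary spectral-database fitting is replaced by transparent window
integration: a metabolite's level is the summed reference-normalized
intensity over ±0.02 ppm windows around each of its signature peaks.
This is coarser than database deconvolution — overlapping signals pool —
but it is fully reproducible and testable.

Per-metabolite ROC curves use all distinct thresholds with trapezoidal
AUC, which equals the tie-adjusted Mann–Whitney statistic (verified in
the tests against an exhaustive pair-count oracle). The multi-marker
ranking orients each AUC above 0.5 and records the implied direction —
an interpretation of "multiple ROC analysis" as oriented univariate
ranking, documented as such.

The accuracy panel is computed from the standard formulas:

- $\mathrm{PPV} = \dfrac{\mathrm{sens}\cdot p}{\mathrm{sens}\cdot p +
  (1-\mathrm{spec})(1-p)}$, $\quad\mathrm{NPV} =
  \dfrac{\mathrm{spec}\,(1-p)}{(1-\mathrm{sens})\,p +
  \mathrm{spec}\,(1-p)}$,
- $+\mathrm{LR} = \mathrm{sens}/(1-\mathrm{spec})$,
  $\;-\mathrm{LR} = (1-\mathrm{sens})/\mathrm{spec}$,

with prevalence $p$ defaulting to the evaluated set's composition and
overridable for projection to an external population. At specificity 1
the positive likelihood ratio is undefined and reported as an explicit
`"N/A"` sentinel, not infinity. Reported percentages round half-up to
one decimal; `verifyReferenceTables()` recomputes every cell of the
published accuracy table from its printed validation counts under these
conventions. Two published predictive-value cells (a PPV printed as
87.6% and an NPV printed as 94.6%) differ by one unit in the last
decimal from their own defining formulas, which give exactly 7/8 = 87.5%
and 52/55 = 94.5%; this package follows the formulas and flags the two
cells (`exactMatch = FALSE`, `withinPrintedPrecision = TRUE`). The serum
tumor-marker rates are the one place a truncation convention is used
(2/32 = 6.25% was published as 6.2%, 155/156 = 99.359% as 99.3%;
half-up rounding reproduces neither), so `markerPanelFromCounts()`
returns exact proportions plus one-decimal truncated percents.

# The synthetic-data generator

Real spectra for this design are not publicly deposited, so the
generator is a first-class module, not a test fixture. It emulates a
500 MHz 1D proton urine spectrum on a 0–9.5 ppm axis of 16384 points:

- the eleven marker metabolites at their published shifts and
  multiplicities, rendered as first-order multiplets (singlet, doublet,
  1:2:1 triplet; unresolved multiplets as binomial 1:4:6:4:1 quintets —
  simple, symmetric, and adjustable) split by J/field ppm with J = 7 Hz
  by default;
- Lorentzian lines with half-width `linewidthHz/fieldMHz` ppm (1 Hz at
  500 MHz); the true line shape is instrument-dependent and unstated in
  the source design, so the natural NMR line shape is the stand-in;
- a TSP reference singlet at 0.00 ppm at fixed concentration, a broad
  class-independent Gaussian residual-water hump at 4.9 ppm (present so
  the exclusion logic is genuinely exercised), and additive white noise;
- per-subject log-normal concentration variation (CV 0.2 by default)
  and a per-subject log-normal dilution factor (log-sd 0.3) that scales
  every metabolite but not TSP — the nuisance that reference
  normalization exists to remove;
- case means shifted by a single fold change (default 2) along each
  signature's direction. The true per-metabolite effect sizes are not
  published, so the fold change is an explicit free parameter rather
  than a guess; baseline concentrations are plausible urinary levels in
  arbitrary units (creatinine dominant, urea and citrate high, valine
  low).

Default cohort sizes mirror the reference screening cohort (156 controls,
92 cases). Everything is deterministic given the config seed, and the
RNG state of the session is restored afterwards.

What the generator does **not** emulate: pH-dependent chemical-shift
drift (so no peak misalignment), the hundreds of background urinary
metabolites (so real spectra are far more crowded and overlapped),
baseline and phase artifacts, FID-level processing, and
between-metabolite correlation beyond the shared dilution factor.
Passing tests therefore demonstrate that the pipeline's statistics and
bookkeeping are correct and that markers of the injected effect size are
recoverable — they do not demonstrate that real urine cohorts separate,
which depends on real effect sizes and matrix effects the simulation
cannot know.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| bin width | 0.0092 | ppm | reference preprocessing grid |
| water exclusion | 4.6–5.2 | ppm | suppressed-water region, dropped whole |
| TSP window | ±0.05 | ppm | reference integral for normalization |
| `nOrth` | 3 | — | matches the reference model structure |
| CV folds | 7 | — | common chemometrics default, configurable |
| holdout fraction | 1/3 | — | per class, `floor`, reproduces 52/30 |
| cut-off | 0.5 | ŷ scale | a priori midpoint of the 0/1 encoding |
| `rThreshold` | 0.6 | \|r\| | annotation threshold; chosen once as a clear-signal level |
| `ppmTol` | 0.02 | ppm | ≈ two bins + line-shape spread |
| `foldChange` | 2 | × | free effect-size parameter of the simulator |
| `withinGroupCv` | 0.2 | — | biological within-group spread |
| `noiseSd` | 0.005 | intensity | spectral noise floor vs. unit TSP peak |
| `dilutionLogSd` | 0.3 | log | urine concentration nuisance |

# Numerical and degenerate-input choices

- Zero or negative reference integral aborts normalization, naming the
  offending sample.
- A constant response, a fold count below 2, classes too small to split,
  mismatched dimensions, unknown multiplicity codes and negative
  concentrations are errors, not warnings.
- `nOrth` at or above the matrix rank is refused (detected both upfront
  and by degenerate-norm checks during deflation).
- Constant bins get STOCSY correlation 0 by convention and are flagged.
- Half-up rounding is implemented explicitly (base R rounds half to
  even) with a 9-digit pre-round absorbing binary representation error.

# Problem sizes used by the test-suite

Unit and property tests run on 2048-point axes with cohorts of 12–60
samples; the marker-recovery study uses 20 seeded replicates of 50 + 50
cohorts at the full 16384-point default; the permutation-null study uses
200 label permutations of a 24 + 24 cohort. These sizes were chosen so
that the full suite exercises every study condition in well under a
minute of simulation time while keeping each check statistically
meaningful.

# Known limitations

- First-order multiplets only; strong-coupling (second-order) patterns
  and pH-sensitive shifts are out of scope.
- Window-integration quantification pools overlapping signals (e.g.
  glycerol and threonine share 3.58 ppm); on real spectra a
  deconvolution step would be required for absolute levels.
- The OPLS implementation is single-response (two-class); multi-class
  designs need one-vs-rest wrapping.
- No confidence intervals on AUC or likelihood ratios, matching the
  scope of the reference analysis.
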