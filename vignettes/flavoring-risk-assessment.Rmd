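---
title: "Methods: flavoring-agent quantification and inhalation risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flavoring-agent quantification and inhalation risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavrisk)
```

## Scope and data model

`flavrisk` models a market survey of flavored cigarettes in which 26
analytes — 25 fragrance allergens restricted for use in food, cosmetics
or toys, plus menthol — are quantified by GC-MS/MS separately in the
tobacco rod, the filter tip and each flavor capsule of every cigarette.
The surveyed design the package emulates comprises 54 cigarettes: 24
without capsules and 30 with capsules, some holding two (30 capsule
cigarettes yielding 42 capsules in total). The unit record is one
compound in one physical part of one cigarette, carrying the detected
instrument level (ng/mL of acetone extract), a censoring status
(`quantified`, `below_loq`, `not_detected`), the dilution factor of any
re-analysis, the extraction volume (25 mL for 0.25 g aliquots of
tobacco and filter tip, 10 mL for whole capsules) and the aliquot
weight.

## Content computation

Levels convert to material concentrations and per-cigarette contents as

$$\mathrm{conc}\ (\mathrm{ng/g}) = \mathrm{level} \times \mathrm{dilution} \times \frac{V\ (\mathrm{mL})}{W\ (\mathrm{g})},
\qquad
C\ (\mathrm{\mu g/cig}) = \mathrm{conc} \times \frac{W}{1000}.$$

The composition cancels the aliquot weight: $C = \mathrm{level}\times
\mathrm{dilution}\times V/1000$. This is both an algebraic identity and
a tested package invariant; it also means the generator can back-compute
instrument levels from target contents without fixing weights
precisely. Dilution re-analysis (extracts falling outside the
calibration range) is modeled as a multiplicative factor on the level,
because diluting the injected extract scales the observed level
linearly.

## Censoring policy

Three-way censoring survives I/O as explicit status literals rather than
sentinel numbers. For exposure estimation, below-LOQ detections are
substituted by the LOQ-equivalent content (LOQ $\times V / 1000$ at
dilution 1) — a deliberately conservative upper-bound imputation —
while non-detects contribute zero, and compounds never detected in any
product are excluded from risk characterization altogether. Substitution
is monotone: it can only raise per-cigarette totals, means and maxima,
which is verified as a property test over generated studies.

## Exposure and risk characterization

For a lifetime smoker,

$$EC\ (\mathrm{mg/m^3}) = \frac{C \times N \times ED \times EF}{IR \times AT} \times \frac{1}{1000},$$

with defaults $N = 13.2$ cigarettes/day, $ED = 82.7 - 13.2 = 69.5$
years, $EF = 365$ days/year, $IR = 14.25$ m$^3$/day and
$AT = ED \times 365 = 25{,}367.5$ days. Two numerical choices matter
here and are fixed by internal consistency of the published figures the
package reproduces: AT is carried in **days** (so $ED \cdot EF / AT =
1$ under the defaults, making $EC = C \times N / IR$ in µg/m³), and the
µg→mg conversion is applied at the EC step. The model assumes 100%
transfer of the flavoring agent from cigarette to smoker — no combustion
loss, mouth spill or filter retention — so exposures are upper bounds.

RCR $= EC/\mathrm{DNEL}$ uses the long-term systemic inhalation DNEL
for the general population; compounds without a DNEL are skipped with a
notice. Reports render exposures to 5 decimals and RCRs to 2
significant figures in scientific notation, the precision at which such
tables are conventionally published. At that precision a published
table is not always self-consistent: recomputing the citral average
exposure from its printed content gives 0.01401 rather than the printed
0.01400 mg/m³, and the methyl eugenol average RCR cannot be recovered
at 2 significant figures from either the printed content or the printed
exposure. These one-ulp discrepancies are rounding artifacts of
independently rounded intermediates, and the package treats them as
such: its own chain always computes from unrounded values.

The averaging denominator behind published "average content" values is
ambiguous when some cigarettes never detect a compound; both policies
(`detected_cigarettes`, the default, and `all_cigarettes`, which differ
exactly by the factor $n_{det}/n_{all}$) are implemented and exposed
rather than guessed.

## Method validation

Calibration is unweighted ordinary least squares with a free intercept —
the simplest model consistent with a published linearity gate of
$R^2 > 0.999$ — since the regression type behind vendor quantification
software is not observable. LOD and LOQ follow the signal-to-noise
definition (levels giving S/N 3 and 10), so LOQ/LOD $= 10/3$ exactly;
applied to a spiked blank matrix the same computation yields the method
detection limit (MDL). The noise input is a user-supplied scalar (RMS of
the blank baseline): chromatogram processing is out of scope, and the
spike level used for matrix MDLs is a parameter because fortification
protocols differ. Recovery (measured/spiked × 100, acceptance band
70–120% by default) and RSD (sample SD/mean × 100, gate < 10%) complete
the validation surface. The regulatory conversion 1 mg/kg = 0.0001%
supports comparison of capsule concentrations against the 0.0002%
leave-on restriction limit.

## Nonparametric battery

Content distributions are strongly right-skewed, so group comparisons
are rank-based, gated by a Shapiro-Wilk pass-through. Kruskal-Wallis
(tie-corrected H, chi-square p on $k-1$ df, with the convention $H = 0$
when all observations are identical) and Mann-Whitney U delegate to the
standard R implementations behind the package's interface; the
Dunn-Bonferroni post hoc is implemented in the package (no installed
implementation exists) from pooled mean ranks with tie-corrected
variance, two-sided normal p-values multiplied by $k(k-1)/2$ and capped
at 1. The exact/asymptotic switch for Mann-Whitney is deterministic and
documented: exact enumeration when the smaller sample has ≤ 8
observations and the data are tie-free, otherwise the normal
approximation with tie and continuity correction. All three agree with
independent enumeration or formula oracles to 1e-8 in the test suite,
and the Kruskal-Wallis test holds its nominal 5% size within
[0.04, 0.06] over 10,000 null simulations (three groups of 15).

PCA uses mean-centering and unit-variance scaling — the standard
chemometric preprocessing — after imputing non-detects as 0, which has
no other defined value; zero-variance columns (compounds never seen)
are dropped. On generated studies the capsule and non-capsule classes
separate in score space (positive mean silhouette), mirroring the
qualitative fingerprinting result such surveys report.

## Synthetic study generator

No raw per-cigarette data are published, so the generator is the
package's study stand-in, parameterized directly by the published
per-part summaries bundled in `content_distributions.csv`: per compound
× part, a detection probability ($n_{det}/n_{total}$) and a log-normal
content distribution matched to the published mean and SD by moments
and truncated to the published [min, max]. The log-normal is the
simplest right-skewed family consistent with means far exceeding
medians; truncation keeps draws inside surveyed ranges (e.g. capsule
menthol within 689.47–2419.50 µg) and gives every cell a finite,
analytically known truncated mean and SD, which the parameter-recovery
tests compare against empirical values. Defaults follow the surveyed
design: 24 + 30 cigarettes, a 0.4 two-capsule fraction (fixed by 42
capsules across 30 capsule cigarettes), and a 5% censor fraction
placing detected measurements between LOD and LOQ — a realistic share
of near-limit detections whose exact rate is unpublished.

Per-compound detection limits are likewise unpublished (only per-matrix
ranges are), so the bundled `detection_limits_synthetic.csv` carries
synthetic representative values spread across the validated ranges,
constrained so that each detected cell's LOQ lies below the lowest
surveyed content — without this the published minima would be
unquantifiable, an internal tension of the published ranges themselves;
for a few tobacco/filter cells the constraint places the LOD slightly
below the published range floor. Instrument levels are back-computed
from drawn contents through the inverted content equations, so
generated datasets pass the same validator as real ones and statuses
re-derive identically from level vs LOD/LOQ.

What the generator does **not** emulate: brand structure (cigarettes
are exchangeable draws), correlation between compounds within a
cigarette, matrix effects, or chromatographic artifacts. Passing tests
therefore demonstrate correctness of the computational pipeline under
a realistic marginal data shape, not fidelity to any particular
product's joint flavor profile.

## Problem sizes and tolerances

Property tests run on studies of 40–60 cigarettes (≥ 1000
cigarette × compound cases); parameter recovery uses a 10,000-cigarette
study, where recovery within 5% relative error is asserted for
design-powered cells only — detection probability ≥ 0.5 and a 3-standard-
error band inside the 5% tolerance, computed a priori from the
configured truncated moments — because low-frequency, high-variance
cells cannot statistically resolve 5% at that sample size. Oracle
agreement for the rank tests is checked to 1e-8; exact arithmetic
identities (parameter derivation, unit conversions, the LOQ/LOD ratio)
are asserted exactly.

## Known limitations

- Exposure is an upper bound: complete-transfer assumption, LOQ
  substitution, and chronic DNELs applied to intermittent exposure all
  bias conservatively.
- The published pairwise "mean difference" statistics of such surveys
  use vendor-specific scalings; the package reports mean-rank
  differences and z-values, which order identically but are not
  guaranteed to match vendor output numerically.
- Synthetic detection limits are representative, not instrument-true;
  users with validated per-compound limits should supply their own CSV
  to `flav_detection_limits()`.
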