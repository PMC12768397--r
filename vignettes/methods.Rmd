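---
title: "Models and methods behind wonemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wonemetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wonemetrics)
```

# The measurement model

wonemetrics implements the computation chain used to develop and validate a
multidimensional stress-resilience index for working adults. The instrument
measures two interrelated systems: a *stress load* domain (Personal Stress,
Work Stress, Burnout) and a *resilience resources* domain (Emotion
Regulation and Coping, Social Connectedness, Purpose and Prosociality,
Sleep, Physical Activity, Dietary Intake, Perseverative Thinking). Each of
the 43 Likert items (1–5 response categories) loads on exactly one
first-order factor; each first-order factor loads on one of the two
second-order factors. The population item covariance implied by the model
is

$$\Sigma \;=\; \Lambda\,(\Gamma\Phi\Gamma' + \Psi)\,\Lambda' + \Theta,$$

where $\Lambda$ holds standardized item loadings, $\Gamma$ the second-order
loadings, $\Phi$ the $2\times 2$ second-order correlation matrix,
$\Psi = I - \mathrm{diag}(\gamma^2)$ the first-order disturbances, and
$\Theta$ the uniquenesses $1-\lambda^2$ plus any residual covariances. All
latent variables and items have unit variance, so $\Sigma$ is a correlation
matrix when residual covariances are absent.

The packaged canonical model (`wone_phase2_spec()`,
`inst/extdata/wone_phase2_model.json`) carries the published standardized
loadings and communalities verbatim. Three of its constants deserve
comment:

* **Dietary Intake second-order loading (0.51).** The publication prints
  six of the seven resilience second-order loadings plus their mean (0.59
  over seven factors). The seventh is back-solved as
  $7 \times 0.59 - 3.62 = 0.51$. This is an inference, documented here and
  overridable by editing the JSON fixture.
* **Cross-domain correlation (−0.71).** The printed stress–resilience
  subscale correlation, applied at the second-order latent level with
  stress items oriented so that raw higher = more stress.
* **Negatively worded resource items** (e.g. loneliness, dwelling) are
  treated as already orientation-corrected, because the published table
  prints positive loadings for them; the simulator performs no hidden
  reversals.

The earlier development-phase model (33 indicators, 6 factors) is not
packaged numerically because its loadings were published only in
supplementary material; only its retention rules (`retention_rules("phase1")`)
are represented.

# The synthetic-data generator

`simulate_responses()` draws the two second-order factors from a standard
bivariate normal with correlation −0.71, builds first-order factors as
$\gamma \cdot \text{parent} + \sqrt{1-\gamma^2}\,\delta$, and items as
$\lambda F + e$ with $\mathrm{Var}(e) = 1 - \lambda^2$ (joint with any
residual covariances), so in continuous mode the sample covariance
converges to $\Sigma$ at $O(1/\sqrt n)$. Ordinal mode thresholds the
continuous responses at standard-normal quantiles $\{-1.5,-0.5,0.5,1.5\}$ —
a symmetric five-category split, chosen because the publication reports
approximately symmetric item distributions (skewness and kurtosis within
±1); thresholds are configurable. True latent scores are returned for
parameter-recovery tests.

Companion generators emulate the remaining study designs: criterion scales
as linear functions of factor scores plus Gaussian noise, sign-flipped for
the higher-is-worse scales (PSS-4, PHQ-8, GAD-7); a two-wave retest with
latent autocorrelation $s$ (wave-2 factors $= s F_1 + \sqrt{1-s^2}\,
\text{innovation}$, items regenerated — default $s = 0.9$, which lands
composite ICCs in the published 0.77–0.90 band once uniqueness noise is
added); and multigroup samples with injectable loading or intercept
perturbations for invariance testing.

What the generator deliberately does *not* emulate: response styles
(acquiescence, straight-lining), missing data (the study reports none),
item wording effects, and non-normal latent distributions. Passing tests
therefore demonstrate the correctness of the statistical machinery under
the stated model, not robustness of the instrument to real-world response
artifacts.

# Exploratory factor analysis

`paf()` is classical iterated-communality principal axis factoring:
communalities seeded with squared multiple correlations, eigendecomposition
of the reduced correlation matrix, update until the largest communality
change falls below `tol` (default $10^{-3}$, the conventional stopping rule
for this algorithm; near-Heywood items make markedly tighter tolerances
converge very slowly). Heywood communalities are capped at 1 and flagged.
Eigenvalues of both the reduced and the unreduced matrix are reported; the
Kaiser eigenvalue-greater-than-one rule is conventionally applied to the
unreduced matrix, and scree data are emitted for human inspection only.

`promax_rotation()` follows the classical two-step scheme: varimax
pre-rotation (Kaiser-normalized), element-wise power-$\kappa$ target
(default $\kappa = 4$, the conventional choice), and an oblique Procrustes
solution, returning pattern, factor correlations, and structure
($=\text{pattern}\times\Phi$). One numerical subtlety: on *population*
correlation matrices the varimax criterion can have an exactly symmetric
saddle point (perfectly balanced bipolar columns), where a single start
from the identity stalls. The pre-rotation therefore runs from several
deterministic starting rotations and keeps the best criterion value; on
sample data all starts agree with `stats::varimax`.

Item retention (`retain_items()`) evaluates rules in a fixed order —
communality, primary loading, cross-loading, primary–secondary gap — so a
dropped item reports exactly one deterministic reason; assignment ties
break toward the lower-index factor.

# The CFA engine

No structural-equation package is part of this artifact's dependency set;
the engine is implemented here in RAM form (directed paths $A$, symmetric
parameters $S$, means $M$; $\Sigma = F(I-A)^{-1}S(I-A)^{-T}F'$), which
covers first-order, second-order, and multigroup mean-structured models
with one parameterization. Choices that matter:

* **Identification.** Each factor's first indicator (or a user-chosen
  marker) has its unstandardized loading fixed to 1, matching the published
  table's convention. The completely standardized solution is invariant to
  the marker choice (tested by re-identification).
* **Estimation.** The normal-theory discrepancy
  $F_{ML}=\ln|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}) - \ln|S| - p$
  (plus $(\bar x-\mu)'\Sigma^{-1}(\bar x-\mu)$ with means; group-weighted by
  $(n_g-1)/(N-G)$) is minimized by quasi-Newton iteration with analytic
  gradients, then polished by Fisher scoring with the expected information
  matrix until the gradient infinity-norm is below $10^{-6}$. $T=(N-G)
  F_{ML}$ with $S$ computed with the $n-1$ denominator.
* **Variances** are optimized on the log scale and bounded below at
  $10^{-3}$: a Heywood case lands on the bound and is flagged; its standard
  error is reported as absent and it is treated as fixed in score tests.
* **Starting values** are deterministic (loadings 0.7, variances 0.5,
  second-order covariance −0.3); no random restarts.
* **Fit indices.** CFI/TLI use the independence baseline with free
  variances (stated explicitly because CFI depends on it); RMSEA
  $=\sqrt{\max(T-df,0)/(df\,(n-1))}$ (times $\sqrt G$ for $G$ groups) with a
  90% CI by bisection of the noncentral $\chi^2$ distribution function;
  SRMR is the root mean squared standardized residual over unique elements
  including the diagonal, averaged over groups.
* **Modification indices** are univariate score tests computed from the
  analytic score and expected information:
  $MI = (N-G)\,s_c^2 / (2\,a_c)$ with $a_c$ the Schur complement of the
  candidate row. Tests verify the MI approximates the actual refit
  chi-square drop within 15% and the expected parameter change approximates
  the freed estimate.
* **Refinement** (`refine_model()`) frees one parameter per iteration —
  the highest-MI candidate intersecting an explicit allowlist, residual
  covariances preferred over cross-loadings — until no allowed MI reaches
  the threshold (published practice: 10). The allowlist is a mandatory user
  input because "theoretically justifiable" is a judgment, never automated;
  the 15 development-phase residual covariances live in unpublished
  supplementary material, so the allowlist mechanism stands in for them.
  Robust (sandwich) standard errors affect only SEs, not estimates or fit,
  and are out of scope; all reported statistics use plain ML. Ordinal
  (polychoric/WLSMV) estimation is likewise out of scope — continuous-mode
  simulation is the default for all oracle tests, since the publication
  does not state how item categories were treated.

# Reliability and validity statistics

Composite reliability uses the published formula
$CR=(\Sigma\lambda)^2/[(\Sigma\lambda)^2+\Sigma(1-\lambda^2)]$; AVE is the
mean of the printed communalities. Both reproduce the formula-consistent
published cells exactly at two decimals (Social Connection 0.94,
Perseverative Thinking 0.89, Physical Activity 0.81, Emotion Regulation
0.89; AVE 0.80 / 0.70 / 0.74). Two published cells are internally
inconsistent with the printed loadings (Work Stress CR prints 0.91, the
formula gives 0.89; one communality prints 1.00 against $\lambda=0.99$);
the tests assert the discrepancy rather than repair it. Display rounding is
half-up at two decimals; internal computation keeps full precision.

Cronbach's alpha carries a Feldt-method F interval (the publication reports
CIs without naming a method; Feldt is the standard choice). McDonald's
omega fits a unidimensional congeneric model with the package's own ML
engine and applies $\omega=(\Sigma\lambda)^2/((\Sigma\lambda)^2+
\Sigma\theta)$.

For test-retest reliability the publication describes a "2-way
mixed-effects model for consistency" but labels it ICC(2,1), which denotes
the two-way random, absolute-agreement form. Both forms are implemented
from the two-way ANOVA decomposition with standard F-based intervals;
ICC(2,1) is the default to honor the printed label, and the discrepancy is
surfaced here rather than hidden. Interpretation bands follow the printed
cut points (0.50/0.75/0.90).

HTMT uses absolute correlations throughout (standard practice; the
publication is silent on signs with reverse-oriented items present) and
flags ratios against the 0.85/0.90 thresholds. Incremental validity is
ordinary nested-model OLS with
$F = (\Delta R^2/q)\,/\,((1-R^2_{full})/(n-p_{full}-1))$; a collinear added
block is reduced to its effective rank with a warning.

# Measurement invariance

`invariance_ladder()` fits the four standard nested multigroup models.
The scalar step equates intercepts and frees first-order latent means in
all but the first group (the standard identification; the publication is
silent). Δ-indices are computed against the immediately preceding step and
judged by the published rules: ΔCFI ≤ 0.01 and ΔRMSEA ≤ 0.015 throughout,
ΔSRMR ≤ 0.03 at the metric step and ≤ 0.01 thereafter. Group-size imbalance
is handled by the $(n_g-1)/(N-G)$ weights. Constrained discrepancies are
asserted non-decreasing along the ladder (nesting), and a reduced-
replication calibration test checks that scalar-step false alarms stay rare
under the null. Partial-invariance search (freeing individual offending
intercepts) is deliberately not implemented: the publication reports full
invariance only.

# Weighting and scoring

Empirical weights regress each standardized criterion on the ten
standardized, orientation-corrected factor scores (unit-weighted item
means with stress factors reverse-coded — the publication says only "the 10
factor scores as predictors"; model-based factor scores are a switchable
alternative the package does not default to). Betas for higher-is-worse
criteria are sign-flipped, combined across criteria by the published
priorities (CD-RISC 25, BRS 22, PSS-4 18, PHQ-8 15, GAD-7 12, WHO-5 8),
clipped at zero, and normalized to 100. Negative averaged betas are clipped
rather than renormalized-signed because clipping is the only rule
consistent with the published statement that all constructs contribute
positively alongside tiny-but-positive printed weights. Normalization
happens after averaging and clipping (the publication does not state the
order).

The hybrid blend is the published 50/50 formula. `apply_floor()` raises
below-floor constructs to exactly 5%, removes the excess from above-floor
constructs proportionally to their weight, iterates to a fixed point (one
pass suffices for the published configuration), renormalizes to 100, and
produces integer display weights by largest-remainder rounding. Fed the
published hybrid column, this reproduces the published integer final
column exactly — including the three constructs that sit below the floor
(Physical Activity 3.6, Work Stress 4.0, Purpose and Prosociality 4.5).
Published half-digit roundings are inconsistent in one cell (hybrid 7.95
printed as 7.9), so printed hybrid half-digits are asserted only where
unambiguous.

Index scoring reverse-codes stress items as $6-x$ on the category scale
(or negation on the continuous scale) so higher index values mean greater
resilience; the full index is the final-weight combination of factor
scores, with unweighted (equal factor weights) and item-level (grand mean)
composites provided for the comparison harness.

# Problem sizes and reproducibility

The analysis drivers under `analysis/` run the whole chain at n = 1000
respondents (500 per invariance group), a scale at which every stage's
sampling error is comfortably inside the tolerances the tests assert while
the full suite stays fast; the parameter-recovery tests use n up to 50,000
where a closed-form population quantity is the oracle. All randomness flows
from explicit integer seeds; reports regenerate byte-identically under a
fixed configuration, and the consolidated report is checked against the
schema document shipped in `inst/extdata/report_schema.json` by the
package's own structural validator.

# Known limitations

* Ordinal responses are generated but always analyzed with Pearson
  covariance ML; polychoric attenuation is visible (and asserted) in
  tests, not corrected.
* The single-factor ML oracle (`stats::factanal`) covers the congeneric
  case only; multi-factor fits are validated against population identities
  and truth recovery rather than a second general-purpose SEM
  implementation.
* Modification indices use expected (not observed) information; agreement
  with actual refit drops is verified at the 15% level, which is adequate
  for ranking candidates but not for reporting MI values as test
  statistics.
* Empirical weights depend on the criterion generating structure; the
  synthetic default reproduces the qualitative shape of the published
  weight profile (emotion regulation dominant, physical activity small),
  not its exact numbers, which would require the original raw data.
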