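---
title: "Methods: signature reactivity scoring, mega-analysis, and directional Bayes factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature reactivity scoring, mega-analysis, and directional Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic-data validation does and does
not establish.

## 1. Pattern expression

A neural signature is a fixed voxel map of regression weights $w_v$; its
expression on a first-level beta image $b_v$ is the dot product
$\sum_v w_v b_v$ over in-mask voxels. The statistic is linear in the beta
image and invariant to voxel enumeration order; any component of the beta
image orthogonal to the weight map contributes nothing. Reactivity is the
within-run difference $\Delta$ = expression(negative) −
expression(neutral), computed per participant, run, and signature.

Choices a user should know about:

* **Grid alignment.** Beta images are resampled onto the signature's grid
  (never the reverse — the signature's weights are fixed quantities),
  trilinearly for intensity images and by nearest neighbour for masks.
  Two grids count as identical when their affines agree element-wise
  within $10^{-4}$ mm; below that tolerance no resampling happens, so
  scores on images already in the signature space are exact.
* **Uncovered voxels.** In-mask voxels with no beta coverage (NaN or
  outside the acquired volume) contribute zero to the sum. The count is
  returned with every score and a warning fires above 10% loss. This
  matches common practice when applying published weight maps to partially
  covered acquisitions while keeping coverage loss visible; the
  alternative (rescaling by covered mass) changes the statistic's units
  between participants and was rejected for that reason.
* **Orientation.** Volumes are reoriented to RAS on load, so files saved
  with different on-disk axis orders score identically. Voxel indices are
  0-based in all affine arithmetic.

ROI means average defined voxels only and warn below 50% coverage.

## 2. Measurement properties

Cronbach's alpha across experimental runs treats runs as parallel
measurements of one session-level trait:
$\alpha = \frac{k}{k-1}\left(1 - \sum_i s_i^2 / s_\text{total}^2\right)$,
with sample variances (denominator $n-1$). Rows with missing cells are
dropped listwise with a message — the formula requires complete rows, and
imputation would fabricate reliability. Alpha is computed on whatever
matrix the caller supplies; the pipeline feeds it per-run reactivity
differences, because the difference score is the quantity every
downstream model consumes. Callers who want reliability of raw condition
expressions can pass those instead.

Forced-choice accuracy is the fraction of participant-runs whose negative
expression exceeds the neutral one, with exact ties counted 0.5 (the
symmetric two-alternative convention; it also makes the measure invariant
to sign flips). Decisions are made per run, not per averaged participant,
which preserves invariance under any strictly monotone transform of the
expressions.

## 3. Effect models

**Within-person effects.** Cohen's $d$ is the mean difference score over
its standard deviation, $t = d\sqrt{n}$, $df = n-1$. The 95% CI on $d$
inverts the noncentral-$t$ distribution at the observed statistic and
converts the noncentrality bounds back to the $d$ scale. This is the
standard exact construction; a normal-approximation CI was rejected
because it is visibly wrong at the sample sizes (tens) this field works
with.

**Group effects.** $d$ is the group mean difference over the pooled SD.
The significance test is Welch's (unequal variances, Satterthwaite df);
the pooled-variance statistic $t = d\sqrt{n_1 n_2/(n_1+n_2)}$ is exposed
separately because default Bayes factors for two-sample designs are
defined on it, and the CI uses it for the same reason.

**Run standardization.** Expression values are not comparable across
scanners, designs, or runs — their scale depends on acquisition gain and
design efficiency. Before pooling, each run-within-study cell is
therefore standardized: divided by the cell SD (`scale_only`; the pooled
intercept is then in Cohen's-$d$ units) or centred and divided by the
cell's pooled-across-groups SD (`center_and_scale`; run intercepts vanish
and the group slope is in $d$ units). The pooled SD is computed per
run-within-study cell, weighted by group degrees of freedom — pooling
across groups within a cell, never across cells, so a between-group mean
difference never inflates the divisor.

**Weighted effect coding.** With groups of sizes $n_{ED}, n_{HC}$ the
codes $+n_{HC}/n$ and $-n_{ED}/n$ differ by one and have size-weighted
mean zero, so a no-intercept regression on them has slope equal to the
raw group mean difference, exactly, for any imbalance. With equal groups
they reduce to ±0.5.

**Mega-analysis.** Scores are pooled across studies at run level in the
two-level Gaussian model $\Delta_{ijk} = \gamma + \zeta_{jk} +
\varepsilon_{ijk}$ with a random intercept per study-participant. No
study-level random terms are included: with as few as three studies their
variance is not estimable, and the fixed effect is interpreted
accordingly (an average over these studies, not a generalization to a
study population). Estimation is REML: the criterion is profiled to the
single variance ratio $\lambda = \sigma^2_\zeta/\sigma^2_\varepsilon$ and
minimized by Brent search on $\log\lambda \in [-12, 12]$ (tolerance
$10^{-10}$), with GLS fixed effects at each step; per-cluster
Sherman–Morrison identities make each evaluation $O(\text{clusters})$. A
boundary fit ($\hat\sigma^2_\zeta = 0$, where the model collapses to OLS
exactly) is reported as a flag, not an error. CIs are Wald with normal
quantiles on the REML standard error — the conventional default for this
model class; profile-likelihood CIs would be more accurate in tiny
samples but the validation below shows Wald coverage is nominal at the
sizes this design produces.

## 4. Bayes factors

**t designs.** The JZS Bayes factor places a Cauchy prior (default scale
0.707, the conventional low-information choice) on the standardized
effect $\delta$ and compares the marginal likelihood of the observed $t$
against the central-$t$ null. One-sided hypotheses truncate the prior to
the hypothesized half-line and double its density, which gives the exact
identity $(\mathrm{BF}_{greater} + \mathrm{BF}_{less})/2 =
\mathrm{BF}_{two\text{-}sided}$, used as a standing test invariant.

Numerically, the marginal likelihood is evaluated through the Student
scale-mixture representation
$f(t\mid\delta) = \int_0^\infty \varphi(tu - \delta\sqrt{n_\text{eff}})\,
u\,g(u)\,du$ with $g$ the density of $\sqrt{\chi^2_{df}/df}$. Exchanging
integrals turns the computation into nested one-dimensional integrals of
strictly positive smooth factors, evaluated on composite Simpson grids in
log space, with node spacing tied to each factor's analytic width (the
Gaussian bump, the support-edge decay rate, the Cauchy core and its
$1/s^2$ tail). This route was chosen over direct quadrature of the
noncentral-$t$ density because R's `dt(..., ncp=)` has an absolute
accuracy floor around $10^{-14}$: when the data strongly contradict the
hypothesized direction the true density sits far below that floor and
direct integration returns noise. The mixture route involves no
cancellation and no underflow for arbitrarily extreme $t$. Each result
carries a `numerical_error` estimate from a half-resolution re-evaluation;
the implementation agrees with a brute-force trapezoid oracle (a million
nodes over a wide noncentrality window) to better than $10^{-6}$ in the
regimes where that oracle is itself trustworthy.

**Mixed model.** For the mega-analytic effect the Bayes factor compares
marginal likelihoods of the random-intercept model with and without the
effect. Random effects integrate analytically (per-cluster
compound-symmetric covariance). Priors: half-Cauchy(0.707) on the
standardized effect $\beta/\sqrt{\sigma^2_\zeta + \sigma^2_\varepsilon}$
in the hypothesized direction, and independent half-Cauchy(1) priors on
the two SD components — weakly-informative defaults of the applied
Bayesian mixed-modelling literature. (The original Bayesian fits this
mirrors used a sampler's default nuisance priors that are not exactly
recoverable; the choice here is documented and its consequences are
bounded by the degenerate-case check below.) The remaining integrals run
over a Gauss–Legendre tensor grid on tangent-transformed SD axes,
windowed around the REML fit at a width of many posterior SDs and refined
until two resolutions agree (the effect dimension is integrated adaptively
inside each node). The computation is deterministic. With singleton
clusters and standardized data it collapses, up to prior differences on
the variance, to the two-sample JZS Bayes factor; the test suite holds
the two within 10%, and in practice they agree to well under 1%.

## 5. The synthetic-data generator

The generator produces the statistical structure the pipeline assumes and
nothing more. Per participant $j$ (group $g$), run $i$, signature $s$:

$$\Delta_{ij} = m_i\,(d_\text{within} + d_\text{between}\,c_g + u_j + e_{ij}),
\qquad u_j \sim N(0, \rho),\; e_{ij} \sim N(0, 1-\rho),$$

so the within-group variance of $\Delta$ is 1 (effects are directly in
Cohen's-$d$ units), $\rho$ is the inter-run intraclass correlation
(Spearman–Brown then predicts run-level alpha, a tested identity), $c_g$
are weighted effect codes (so the population mean is $d_\text{within}$
and the ED−HC difference is $d_\text{between}$), and $m_i$ are run SD
multipliers emulating design effects — they scale mean and SD jointly,
leaving per-run $d$ unchanged, which is precisely the invariance the
run-standardization step exploits. Neutral-condition expression is a
unit-normal baseline; the negative condition adds $\Delta$.

Voxel level: each signature is a smoothed Gaussian random field with
$\sum w_v^2 = 1$, paired with an exactly orthogonal unit-norm nuisance
map $q$. A beta map is $b = e\,w + z_1 q + \text{white noise}$; scoring
against $w$ returns $e$ plus error of variance `noise_iid_sd`², and the
$q$ component is invisible to a correct scorer (a tested invariant —
a scorer that mixes in anything beyond $w$ fails it). Defaults: 8×8×8
grids (512 voxels) keep full-pipeline tests fast; the named
`three_study` preset carries the sample structure 29+28 and 20+20
participants × 3 runs, 62+33 × 1 run. One root seed drives everything
through per-participant-and-signature substreams, so adding a signature
does not perturb existing draws and every dataset is bit-reproducible.

What the generator does **not** emulate: spatial autocorrelation of real
BOLD noise, anatomical structure, inter-subject registration error,
hemodynamic or design confounds, non-Gaussian heavy tails, or any
dependence of signature weights on real brains. Passing recovery tests
therefore validates the *statistical* chain (scoring → standardization →
models → inference) under the assumed generative structure; it says
nothing about whether a real signature measures what it claims.

## 6. Validation problem sizes

The recovery studies in the test suite use sizes chosen to make
Monte-Carlo error, not walltime, the binding constraint: 500 replicates
of 200 participants × 2 runs for mega-analytic recovery and CI coverage
(within-person effect 0.5, group effect 0.4, intraclass correlation 0.5),
alpha against Spearman–Brown at 500 participants × 3 runs, forced-choice
accuracy against $\Phi(d)$ at 10,000 participants, and smaller
simulations (tens of replicates) for Bayes-factor direction checks, whose
per-replicate quadrature is comparatively expensive. Recovery is asserted
within two Monte-Carlo standard errors of the replicate mean and coverage
within 95% ± 2%. One caveat built into those margins: scaling by a
run-cell *sample* SD inflates the estimand by the standard
$\approx 1 + 3/(4n)$ small-sample factor, so recovery checks at modest
cell sizes sit a fraction of a Monte-Carlo SE above the nominal truth;
the chosen cell size of 200 keeps that bias well inside the band. The
implementation follows the field's convention of scaling by the sample SD
rather than applying a small-sample correction.

## 7. Known limitations

* No 4-D time-series handling, no first-level GLM, no spatial
  preprocessing — beta images are the input contract.
* No study-level random effects (deliberate, see §3) and no random
  slopes; no meta-regression on moderators; no multiplicity correction.
* Wald CIs for the mixed model can undercover in designs far smaller than
  those validated here.
* The mixed-model Bayes factor's variance-component priors are a
  documented default, not a reconstruction of any particular sampler's
  defaults; sensitivity to halving/doubling those prior scales is small
  in the regimes tested but has no formal bound.
* `pattern_expression` trusts the caller's spatial normalization: images
  are aligned by affine grid mapping only, never warped.
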