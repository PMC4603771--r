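---
title: "A two-phase stochastic model of PRC1 over the cell cycle: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-phase stochastic model of PRC1 over the cell cycle: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prc1dyn)
```

## The model and its assumptions

PRC1 is expressed at high levels through S/G2/M and drops sharply after
mitotic exit, so over one cell cycle its single-cell trajectory is V-shaped:
a degradation phase followed by an accumulation phase. `prc1dyn` models one
cycle with piecewise-exponential kinetics,

$$X_1 = X_0 e^{-a T_1}, \qquad X_2 = X_1 e^{b T_2},$$

and couples the per-cell kinetic parameters through four linear
relationships with additive Gaussian noise:

$$
\ln a = b_1 + b_{10} X_0 + \varepsilon_a,\quad
\ln T_1 = b_2 + b_{21} \ln a + \varepsilon_{T_1},\quad
\ln b = b_4 + b_{41}\ln a + b_{43} X_1 + \varepsilon_b,\quad
T_2 = b_5 + b_{52} T_1 + \varepsilon_{T_2}.
$$

At division the protein is split unequally: one daughter receives the
fraction $U \sim \mathrm{Beta}(\alpha,\alpha)$ of $X_2$, the other the rest,
so $E(U)=1/2$ and $V(U)=(8\alpha+4)^{-1}$. The model assumes no cell death,
no quiescence and no explicit cell-cycle-phase structure; protein amounts
are continuous positive reals in arbitrary fluorescence units (the
coefficient magnitudes, e.g. $b_{10}\sim 10^{-6}$–$10^{-5}$, put the
operating scale near $10^4$–$10^5$ a.u.), and time units are abstract,
nominally hours (the $T_2$ intercepts near 20 are consistent with that
reading).

Four fitted parameter sets ship as JSON fixtures (`prc1_params(1)` …
`prc1_params(4)`). Set 2 differs structurally: its degradation-duration
equation is on the identity scale ($T_1 = b_2 + b_{21}\ln a$), and its
$\ln a$–$X_0$ slope is positive as printed in its source even though the
corresponding raw-data correlation has the opposite sign; the fixture
transcribes the published coefficients without correction.

### The noise-dispersion convention

The published dispersions are written in an `N(0, v)` notation that does not
say whether `v` is a variance or a standard deviation. Both readings are
implemented (`noise_convention = "sd"` or `"var"`, carried inside the
parameter object). The default is the standard-deviation reading, for two
reasons measured with this package: (i) under it, long-run simulations of
parameter set 1 reproduce the reference simulation-based correlations
(the quantities `scripts/acceptance.R` recomputes) within a few hundredths,
and (ii) under the variance reading, parameter set 2 becomes numerically
explosive — occasional runaway birth amounts drive the identity-scale
$T_1$ far above $b_5/|b_{52}|$, the $T_2$ rejection loop then cannot find a
positive value, and the simulation fails. The convention is therefore
frozen at `"sd"`.

### Positivity by rejection

A Gaussian draw can make an identity-scale $T_1$ or a $T_2$ non-positive.
Such a draw is rejected and its noise term redrawn — the noise is Gaussian
conditional on positivity — per equation, not per cell, so an unlucky
$T_2$ draw does not resample the whole cycle. More than 1000 consecutive
rejections for one equation raises an error naming the equation; under the
shipped parameter sets rejections are rare (the acceptance fraction is
near 1).

## The branching simulator

`simulate_pedigree()` grows a binary tree of cycles from one ancestor,
breadth-first with vectorised draws in cell-id order from a single seeded
RNG stream. Because the traversal order is fixed, one seed determines the
whole pedigree byte-for-byte; this achieves the reproducibility of per-node
RNG streams without hand-rolling a splittable generator R does not provide
natively.

**Ancestor default.** The ancestor's birth amount defaults to the parameter
set's own deterministic equilibrium (the root of $X_0 = \phi(X_0)/2$,
computed at construction), not a fixed constant. The operating scales of
the four parameter sets differ by an order of magnitude (equilibria
$\approx 1.46\times10^5$, $1.49\times10^4$, $7.1\times10^4$,
$5.0\times10^4$ a.u. for sets 1–4), and starting set 2 at $10^5$ a.u. drives
$a = \exp(-3.37 + 7.82\times10^{-5}\cdot10^5) \approx 85$, collapsing the
minimum to $\sim10^{-185}$ a.u., from which recovery takes hundreds of
generations. Starting at the equilibrium makes a short burn-in (default 5
generations) equally meaningful for every set; post-burn-in statistics are
insensitive to halving or doubling the ancestor amount (tested).

**Memory cap.** An uncapped tree has $2^{g+1}-1$ nodes. With `cap` set, when
a generation would exceed it, $\lfloor \mathrm{cap}/2\rfloor$ parents are
chosen uniformly at random and both daughters of each are kept. Uniform
parent subsampling is unbiased for cross-sectional statistics and, unlike
subsampling daughters, keeps every retained sibling pair intact — which the
sibling time-point correlations need.

**Exact conservation.** Daughter amounts are computed as
`right = X2 - U*X2; left = X2 - right`, which makes `left + right == X2`
exact in floating point (a Sterbenz-subtraction argument; verified on
millions of draws), not merely close.

## The synthetic-data generator

`generate_dataset()` emulates measured single-cell trajectory tables: the
branching model is simulated past burn-in, each cell is sampled on a
regular grid of spacing `dt` (default 0.25 time units, i.e. ≥ 80 samples
over a ~22-unit cycle), every sample is multiplied by lognormal measurement
noise with unit median and coefficient of variation `measurement_cv`
(default 0.05 — fluorescence error is positive and scale-proportional),
and a fraction `outlier_fraction` (default 0.1) of trajectories is
corrupted so that their end/start fold change lands uniformly in
`outlier_ratio_range` (default 10–50). Corruption rescales the accumulation
segment smoothly, mimicking a mis-identified cycle boundary: the corrupted
trajectory keeps a plausible V shape but an absurd fold change.

What the generator does *not* emulate: imaging, segmentation or tracking
errors beyond the fold-change mechanism, missing frames, photobleaching, or
any dependence of measurement error on expression level beyond
proportionality. Tests passing on this generator therefore validate the
pipeline's statistical machinery, not its robustness to every failure mode
of real microscopy data.

## Feature extraction and outlier screening

`extract_features()` reduces a trajectory to a cycle record: $X_0$ and
$X_2$ are the first and last samples; the phase switch is the argmin of a
centred moving average (default window 5 samples, shrinking at the edges),
with $X_1$ the *raw* value there; and the rates invert the kinetics,
$a = \ln(X_0/X_1)/T_1$, $b = \ln(X_2/X_1)/T_2$ — exactly consistent with how
the model defines them (per-phase log-linear regression would estimate
slightly different quantities under discretisation). Trajectories whose
minimum sits at an endpoint have no two-phase structure and are rejected
with a reason.

Two discretisation effects matter and were measured. First, the grid
offsets the argmin by up to `dt`, biasing $T_1$ up and $X_1$ up by $O(dt)$;
at `dt = 0.25` all variables are recovered within ~2% (median) on
noise-free data. Second, the smoothing window itself shifts the argmin
toward the shallower (accumulation) side of the V; on noise-free data this
adds a systematic $T_1$ bias of roughly two grid steps. Smoothing exists to
stabilise the argmin under measurement noise — on noise-free data
`smoothing_window = 1` is the right setting, and the package's
parameter-recovery checks use it with `dt = 0.05` so that grid bias stays
below sampling error at $n = 2000$ cells.

`tukey_filter()` screens records by the fold change $r = X_2/X_0$ with
type-7 (linear interpolation) quartiles and fences $Q_1 - k\,\mathrm{IQR}$,
$Q_3 + k\,\mathrm{IQR}$. The default multiplier is $k = 2.5$, not the
textbook 1.5: the stationary fold-change distribution of the fitted model
is strongly right-skewed (97.5th percentile ≈ 6 against a median ≈ 2), so
the 1.5 fence — calibrated for near-symmetric distributions — would discard
2–4% of intact cells, while corrupted trajectories sit at fold changes of
10–50, far above either fence. At $k = 2.5$ the screen removes every
injected outlier and about 1% of intact cells in the package's operating
tests. Both `k` and the sidedness are arguments; re-applying the filter
with its own frozen fences is idempotent.

## Estimation conventions

`fit_regressions()` fits the four equations by ordinary least squares on
their exact model forms. Residual dispersions use the unbiased $n-p$
denominator and are reported in both conventions. Coefficients of variation
use the $n-1$ variance denominator. Correlation tables are plain Pearson
product-moment over the ten variables $X_0, X_1, X_2, T_1, T_2, T_1+T_2, a,
\ln a, b, \ln b$; zero-variance variables yield undefined (`NA`) entries,
never 0. The pipeline default is filter-then-fit.

`estimate_division_asymmetry()` inverts the balanced-growth identity
$cv_U^2 = (cv_{X_0}^2 - cv_{X_2}^2)/(cv_{X_2}^2+1)$ and then
$\alpha = (1/V(U) - 4)/8$ with $V(U) = cv_U^2/4$. If the cross-sectional
spread of $X_0$ does not exceed that of $X_2$ the asymmetry is
unidentifiable and the estimator fails reporting both cv values.

## The deterministic reduction

With noise suppressed the model defines maps $X_2 = \phi(X_0)$ and
$T = \psi(X_0)$. `find_equilibria()` locates roots of $\phi(x)/2 - x$ by a
512-point log-spaced scan over $(10^3, 10^6)$ a.u. followed by bisection to
relative tolerance $10^{-8}$; scan-then-bisect (rather than a single Newton
run) is deliberate because $\phi$ need not be monotone — parameter set 2's
$\phi$ has an interior maximum near $8.5\times10^3$ a.u. and decays beyond
it. Stability is flagged by the magnitude of the central-difference
derivative of $\phi/2$ at the root (step $10^{-4}x$) being below 1 — a
testable convention, since the sources present equilibria only graphically.
Parameter set 1's $\phi$ rises up to $X_0 \approx 1.35\times10^5$ and then
plateaus (≈ 4–6% decline by $4\times10^5$); the near-zero map derivative at
the equilibrium (−0.015) is the quantitative face of the "well-tuned
circuit" behaviour: birth-amount perturbations are erased in one
generation.

`asymmetric_iteration()` runs the one-daughter recursion
$X_0' = U\,\phi(X_0)$, the deterministic model with division asymmetry as
the only randomness. Under parameter set 1 the birth amounts oscillate with
the split fraction while the division amounts barely move
($\operatorname{var}(\ln X_2) < \operatorname{var}(\ln X_0)$ in every
seeded run), and in the $\alpha \to \infty$ limit the iteration stays at
the equilibrium to within $10^{-3}$.

## Population reporting

`simulated_correlation_table()` simulates from the default ancestor until
at least `n_cells_target` cells (default 10,000) exist beyond the burn-in
generation and correlates their cycle records. `timepoint_correlations()`
interpolates each cell's protein level at percentages of its own cycle span
(0–100 in steps of 5 by default), linearly on the log-value scale, and
correlates related pairs: parent–progeny (both daughters by default, a
single random daughter optionally) or sibling–sibling (both orderings of
each pair, so the matrix is exactly symmetric). Entries backed by fewer
than `min_pairs` pairs, or with zero variance, are `NA`. The grid,
interpolation scale and pairing are all arguments; no published numeric
anchor exists for these heatmaps, so their tests are property-based
(symmetry, reproducibility, sign structure).

One measured caveat: under parameter set 2 the correlation between $X_0$
and the raw rate $a$ is dominated by the exponential right tail of the
$X_0$ distribution and fluctuates by about ±0.1 between seeds even at
$n = 3\times10^4$ cells (its log-scale counterpart, corr$(X_0, \ln a)$, is
stable at ≈ 0.69). The acceptance script reports the value as computed;
single-seed values near 0.6 are typical. By contrast the sibling birth-time
correlation is strongly *positive* (~0.8): conditioned on the parent the
complementary split pulls siblings apart, but marginally the shared
division amount dominates at the fitted asymmetry
($V(U) \approx 0.004$ against $cv_{X_2} \approx 0.3$).

## Problem sizes and runtime

The shipped tests use: 10,000 post-burn-in cells for correlation tables
(seconds per parameter set); 2000 cells at `dt = 0.05` for parameter
recovery (a few seconds per set); $10^6$ Monte-Carlo draws for the
split-fraction cv identity; 500-cell synthetic data sets across 10 seeds
for the outlier screen; and 550-step iterations across 10 seeds for the
regulation property. These sizes were chosen so that Monte-Carlo error is
comfortably below each check's tolerance.

## Known limitations

- The model carries no mechanism for cell death, quiescence or phase
  structure; it describes one protein's bulk kinetics, not the cell-cycle
  machinery.
- The regression structure is fitted by plain OLS; measurement error in the
  regressors (inevitable after feature extraction) is not modelled, which
  is why the recovery checks control discretisation error by grid
  refinement rather than an errors-in-variables correction.
- The asymmetry estimator assumes balanced exponential growth and
  independence of $U$ from $X_2$; it is a moment inversion, not a
  likelihood fit, and inherits the sampling noise of two cv estimates.
- Parameter set 2 is qualitatively fragile: its non-monotone $\phi$ admits
  collapse-and-recover excursions, and several of its raw-scale statistics
  are heavy-tail sensitive (see above).
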