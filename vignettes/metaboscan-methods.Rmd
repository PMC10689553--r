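---
title: "Scanning a metabolome for associations: the models behind metaboscan"
author: "metaboscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning a metabolome for associations: the models behind metaboscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboscan)
```

## The problem

A metabolomics study measures hundreds of small molecules per biosample and
asks which of them vary with one trait of interest — age, BMI, an exposure.
The columns of such a table are statistically unruly: every metabolite lives
on its own scale, distributions are skewed in metabolite-specific ways,
variances are heterogeneous, instruments report values below a limit of
quantification (LOQ) only as "at most LOQ", limited precision produces
blocks of tied values, metabolites are correlated in subgroups, and cells
are missing.  Any fixed-distribution regression applied uniformly across
such columns mis-specifies most of them, and testing hundreds of models
without exploiting their correlation wastes power.

`metaboscan` addresses both issues with a single construction: a monotone
**transformation model** per metabolite and metameter, and **joint max-t
inference** across all of the resulting marginal models.

## The per-metabolite model

For metabolite $Y_i$ and exposure $X$ the model is

$$P(Y_i \le y \mid x) = F_\varepsilon\!\big(h_i(y) - x^\top\beta_i\big),$$

where $F_\varepsilon$ is a fixed error distribution (standard normal by
default — a Box–Cox-type model; standard logistic optionally, which makes
$\beta$ a log-odds ratio valid at every response cutoff, i.e. continuous
outcome logistic regression) and $h_i$ is a strictly monotone
transformation *estimated from the data* — the most likely transformation.
Because $h_i$ absorbs the marginal distribution of $Y_i$, no distributional
assumption is made about the metabolite itself, and effects of differently
scaled metabolites become comparable: $\beta_i$ is a shift on the latent
standard-normal (or logistic) scale per raw unit of the exposure metameter.
Positive $\beta$ means the metabolite increases with the exposure.

$h_i$ is parameterized in a Bernstein polynomial basis of order $M$ on a
bounded support $[a, b]$:
$h(y) = \sum_{k=0}^{M} \theta_k \binom{M}{k} z^k (1-z)^{M-k}$ with
$z = (y-a)/(b-a)$.  Non-decreasing coefficients $\theta$ make $h$
monotone, and the endpoint values are interpolated exactly
($h(a)=\theta_0$, $h(b)=\theta_M$).  The optimizer works on the
unconstrained vector $\gamma$ with
$\theta = \mathrm{cumsum}(\gamma_1, e^{\gamma_2}, \dots, e^{\gamma_{M+1}})$,
which keeps $h$ weakly monotone for every $\gamma$.

### Censoring and ties

The likelihood mixes three observation types per metabolite:

* **exact** values contribute the density term
  $\log f_\varepsilon(h(y) - x^\top\beta) + \log h'(y)$;
* values at or below the LOQ are **left-censored** statements and
  contribute $\log F_\varepsilon(h(\mathrm{LOQ}) - x^\top\beta)$;
* **tied** values are read as roundings of an underlying continuous truth
  and are broken into **interval** observations contributing
  $\log\{F_\varepsilon(h(u) - x^\top\beta) - F_\varepsilon(h(l) -
  x^\top\beta)\}$.

The interval endpoints for a tie are this package's own convention, since
"treat ties as interval-censored" does not by itself fix endpoints: a tied
value $t$ receives the interval between the midpoints to the adjacent
distinct observed values, and the outermost tied values extend outward by
half the nearest inter-value gap.  Any duplicated uncensored value counts
as a tie (no minimum multiplicity), because the measurement-precision
mechanism that creates ties applies to every duplicate.  Values exactly
equal to the LOQ are censored ("reported at the LOQ" conventionally means
at or below it).  Missing cells are kept as explicit markers and excluded
per model at fit time.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `order` | 6 | Bernstein order $M$; $M+1$ transformation parameters. Order 1 reduces to a linear $h$, i.e. the Gaussian linear model under the probit link. Larger orders buy flexibility at the price of weaker identification under heavy censoring. |
| `supportMargin` | 0.1 | the support $[a,b]$ is the observed anchor range extended by this fraction on each side, giving $h$ room beyond the extreme observations. |
| `link` | `"probit"` | error distribution; `"logit"` switches to continuous outcome logistic regression. |
| `tiePolicy` | `"interval"` | `"none"` keeps ties exact (useful to quantify the impact of the tie correction). |
| `level` | 0.95 | simultaneous coverage of the max-t intervals. |
| `includeLog`, `logBase` | `TRUE`, $e$ | whether and how the logarithmic metameter is built. Metameters are never centered or scaled: effects are per raw unit (e.g. per year and per log-year of age). |
| `family` | `"all"` | the max-t family spans all $2p$ models; `"per-metameter"` corrects the two panels separately. |
| `seed` | 20230101 | seed of the quasi-Monte-Carlo quadrature; fixing it makes scans bit-reproducible. |

## Metameters

The exposure enters twice: unmodified ("arithmetic") and as its natural
logarithm ("logarithmic"), so a metabolite whose dependence flattens at
higher exposures is captured by the log shape while a proportional trend
is captured by the linear one.  With $p$ metabolites this yields $2p$
marginal models and the joint null "no association under either shape" per
metabolite.

## Joint inference

Each model is fitted separately by maximum likelihood (analytic gradients
and Hessian, Newton iterations under a trust region with a BFGS fallback
and one deterministic jittered restart; a fit is declared converged when
the parameter-scaled score norm falls below $10^{-4}\max(1,|\ell|)$).
Covariances *across* models come from the multiple-marginal-models
construction: with per-observation scores $s_{ij}$ and observed
informations $I_j$, block $(j,k)$ of the joint covariance is
$I_j^{-1}\big(\textstyle\sum_i s_{ij} s_{ik}^\top\big) I_k^{-1}$,
and the entries of the tested metameter coefficients are extracted.
Samples missing in one model contribute zero score rows there, which keeps
models with different complete-case sets in a single joint frame (an
estimating-function convention worth knowing about when comparing with
software that assumes one shared frame).  Under heavy censoring a
Bernstein increment can collapse to zero, leaving a flat, uninformative
transformation direction; such directions are projected out of the
information inverse by an eigenvalue-thresholded pseudo-inverse rather
than dropping the model.

From the estimated correlation $R$ of the standardized statistics, the
equicoordinate critical value $c_\alpha$ solves
$P(\max_j |Z_j| \le c) = 0.95$ under $Z \sim N(0, R)$.  Simultaneous
confidence intervals are $\hat\beta_j \pm c_\alpha \cdot se_j$ and
single-step adjusted p-values are $1 - P(\max_j |Z_j| \le |t_j|)$.
Exploiting $R$ makes the correction strictly less conservative than
Bonferroni whenever metabolites (or the two metameters of one metabolite,
which are typically highly correlated) are dependent, while still
controlling the familywise error rate; $c_\alpha$ always lies between the
unadjusted and the Bonferroni quantile, and this bracket is enforced
against quadrature noise.

Rectangle probabilities are evaluated exactly in one dimension, by
deterministic Miwa quadrature for small non-singular problems (up to four
dimensions), and otherwise by seeded Genz–Bretz randomized quasi-Monte-Carlo
integration (`mvtnorm`), so all results are deterministic given the seed.
The critical value is found by bracketed root search with a tolerance of
about $10^{-4}$ on the probability scale; simulation studies inside the
test suite use a decision-grade tolerance of $2\times10^{-3}$.  Adjusted
p-values are clamped from below by the unadjusted two-sided p-value, which
the single-step construction dominates theoretically; the clamp removes
quadrature-noise violations of that ordering.

## Numerical choices and degenerate inputs

* Starting values: $\beta = 0$; $\theta$ from a ridge-stabilized
  regression of the link-transformed, Winsorized (by $1/2n$) empirical CDF
  on the basis, monotonized by a running maximum.
* Underflowing interval terms are floored at $e^{-700}$ instead of
  $-\infty$ so a single extreme observation cannot destroy a fit.
* Basis evaluation clamps arguments within $10^{-9}$ (relative) of the
  support edges; anything further out is an error.
* A metabolite is *skipped with a reason* — never a crash — when it is
  degenerate: fewer than three observed values, a single distinct
  uncensored value, an LOQ at or above the maximum (everything censored),
  or too few usable observations for the parameter count.  Non-converged
  fits keep their table row (flagged `converged = FALSE`) but are excluded
  from the joint correlation.
* Rescaling a metabolite by a positive constant leaves $\hat\beta$
  unchanged; the maximized log-likelihood shifts by the density Jacobian
  $-n_\mathrm{exact}\log c$, as it must for continuous observations.

## The synthetic-data generator

`simulateMetabolome()` emulates the features the scan must survive, with
known ground truth: an age-like exposure $X \sim U(18, 80)$ years; latent
Gaussian regressions $Z_i = \beta_i m_i(X) + \varepsilon_i$ with
$m_i$ the identity or the natural log and block-equicorrelated
standard-normal errors; heterogeneous positive scales and monotone
distortions (identity, exponential, cubic, logistic) mapping $Z_i$ to the
reported abundance scale; rounding to create ties; LOQ reporting at the
per-metabolite `censorFrac` quantile; and a missingness mask.  True
effects are expressed on the latent standard-normal scale per metameter
unit, so recovery can be checked without back-transforming.

What the generator does *not* emulate: instrument-level artifacts (batch
effects, drift, peak-integration errors), informative missingness,
non-monotone distortions, and heavy-tailed error laws.  Passing tests on
synthetic data therefore demonstrate correctness of the estimation and
inference machinery under the model's assumptions, not robustness to every
failure mode of real spectra.

## Study sizes used by the checks

The test suite calibrates the machinery at sizes chosen to give stable
Monte-Carlo answers on a single CPU: the familywise error rate is
estimated from 500 global-null replicates of a 20-metabolite, 200-sample
scan with block correlation 0.5 (40 models per replicate); power and
recovery use 200 replicates of a 20-metabolite, 300-sample design with one
planted arithmetic effect (0.05 per year) and one planted logarithmic
effect (1.5 per log-year) among 18 nulls.  These effect sizes are
deliberately clear-cut — roughly ten marginal standard errors — so that a
correct implementation flags them in the majority of replicates while the
18 null metabolites calibrate the false-positive side.

## Worked example

```{r example, eval = FALSE}
library(metaboscan)

d <- simulateMetabolome(simConfig(
  n = 120, p = 6, beta = c(0.06, rep(0, 5)),
  distortion = c("identity", "exp", "cube", "logistic", "identity", "exp"),
  censorFrac = 0.1, roundDecimals = c(NA, 1, NA, 2, NA, NA),
  blockSize = 3, blockRho = 0.5, missingFrac = 0.03, seed = 11))

res <- metaboScan(d$abundance, d$metadata, exposure = "age",
                  loqMap = d$truth$loq)
resultsTable(res)
forestPlot(res, "arithmetic")
```

## Known limitations

* A large censored fraction weakens identification of the Bernstein
  coefficients; the scan degrades gracefully (flat directions are
  projected out, fits may be flagged) but intervals for such metabolites
  are wide and should be read cautiously.
* The joint inference is asymptotic; at small $n$ with many parameters per
  model the familywise error can drift above nominal.
* Right-censoring, stratified baselines and ordinal exposures are out of
  scope; only arithmetic and logarithmic metameters are built in.
* Adjusted p-values for very large families cost one high-dimensional
  rectangle probability per model; for thousand-model scans the interval
  display (one critical value) is the cheaper summary.
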