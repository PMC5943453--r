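---
title: "Demographic trends from constant-effort banding data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic trends from constant-effort banding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Constant-effort mist-netting networks such as MAPS (Monitoring Avian
Productivity and Survivorship) band and recapture birds at fixed stations
with a standardized protocol every breeding season. For a declining
migratory songbird, such data can separate the demographic components of
the decline: is abundance falling because breeding productivity fell, or
because adult survival and the recruitment of new breeders fell? The
answer points to the breeding grounds or to the non-breeding period as the
likely driver. `mapsdem` implements the full analysis as a reusable,
tested pipeline: a transient Cormack-Jolly-Seber (CJS) survival model with
a residency mixture, a Poisson log-linear abundance model, a binomial
relative-productivity model, recruitment derived from the joint posterior,
and a synthetic-data generator that makes every stage testable without
access to any restricted banding dataset.

## The models

### Abundance

The annual count of adults $C_{k,s,t}$ at station $s$ of region $k$ in
year $t$ is an index of breeding density:

$$C_{k,s,t} \sim \mathrm{Poisson}(\lambda_{k,s,t}), \qquad
\log \lambda_{k,s,t} = \alpha_{\lambda_k} + \beta_{\lambda,1_k} t
 + \beta_{\lambda,2}\,\mathrm{HF}_s + \beta_{\lambda,3}\,\mathrm{EF}_{s,t}
 + \omega_{\lambda_s} + \varepsilon_{\lambda_{k,s,t}}.$$

$\mathrm{HF}_s$ is the human-footprint index around the station (a 0-50
composite of built environment, agriculture, population, lights, roads,
rail and waterways), $\mathrm{EF}_{s,t}$ the mist-netting effort in
net-hours, $\omega_{\lambda_s}$ a station random effect and
$\varepsilon$ an observation-level normal deviate on the log scale —
lognormal-Poisson overdispersion. Counts are an index, not a
detection-corrected abundance; station-years with no operation are
missing, never zero.

### Productivity

Relative breeding productivity is the probability that a captured
individual is a juvenile:

$$\mathrm{JUV}_{k,s,t} \sim \mathrm{binomial}(p_{k,s,t}, N_{k,s,t}),
\qquad \mathrm{logit}(p_{k,s,t}) = \alpha_{p_k} + \beta_{p,1_k} t +
\beta_{p,2}\,\mathrm{HF}_s + \omega_{p_s}.$$

Because the juvenile proportion needs at least one adult to be
informative, stations whose captures were all juveniles are dropped.

### Survival with transients

Encounter histories of marked adults are modelled with a transient CJS
formulation. A newly captured bird is a local resident with probability
$\pi$; transients pass through and are never available for recapture.
Residents captured in more than one within-season sampling period are
*pre-determined* residents (probability $\rho$); this flag is data and
anchors the residency mixture. Apparent survival $\phi$ and residency
$\pi$ are logit-linear:

$$\mathrm{logit}(\phi_{i,t}) = \mu_\phi + \beta_{\phi,1_k} +
\beta_{\phi,2}\,\mathrm{sex}_i + \beta_{\phi,3}\,\mathrm{HF}_s +
\beta_{\phi,4_k} t + \omega_{\phi_s},$$
$$\mathrm{logit}(\pi_{i,t}) = \alpha_\pi + \beta_{\pi,1_k} +
\beta_{\pi,2}\,\mathrm{sex}_i + \beta_{\pi,3}\,\mathrm{HF}_s +
\omega_{\pi_s},$$

with recapture $pr$ and pre-determination $\rho$ carrying an intercept, a
sex effect and a station random effect each. Conditional on first capture
at occasion $f$ with last detection at $l$, a history contributes

$$P = \begin{cases}
\pi\,\rho\;P_{\mathrm{CJS}} & d = 1\\[2pt]
\pi\,(1-\rho)\,P_{\mathrm{CJS}} + (1-\pi)\,
\mathbf{1}[\text{no detection after } f] & d = 0
\end{cases}$$

where $P_{\mathrm{CJS}} = \prod_{t=f}^{l-1}\phi_t\,
pr^{y_{t+1}}(1-pr)^{1-y_{t+1}} \cdot \chi_l$ and $\chi$ is the standard
never-seen-again recursion $\chi_T = 1$, $\chi_t = (1-\phi_t) +
\phi_t(1-pr)\chi_{t+1}$. The compiled likelihood and a plain-R
per-history evaluation agree to $10^{-12}$, and the outcome probabilities
over all detection vectors and flags sum to one — both are enforced by
tests.

### Derived recruitment

With abundance and survival fitted jointly in one sampler run,
recruitment is a per-draw identity, not a new estimate:

$$\mathrm{rec}_{k,t+1} = N_{k,t+1} - N_{k,t}\,\phi_{k,t}.$$

$N_{k,t}$ is the station sum of expected counts at mean effort with
$\varepsilon = 0$ (a per-station average is available as an option), and
$\phi_{k,t}$ is the equal-weight average of male and female survival at
mean covariates — the least-assumptive pooling of a sex-structured
$\phi$ into a regional rate. Draws can be negative when the index falls
faster than survival alone allows; they stay in the series but are
excluded (and counted) from the log-linear trend fit. Per-draw
least-squares on $\log \mathrm{rec}$ is the default trend estimator; an
endpoint ratio would weight only the first and last years and is not
used.

## Covariates, regions and filters

* Regions: west of 102°W is *west*; otherwise stations south of 47°N and
  east of a configurable meridian (default 90°W) are *east*; the rest are
  *central*. The boundary meridian itself goes central (strict
  inequality); coordinates outside a plausible bounding box are flagged,
  never silently classified. The eastern polygon of the original network
  is geographic rather than algorithmic, so the meridian is a config
  value and real classifications should be audited.
* Footprint: rasters exist for 1993 and 2009 only. A station active in
  both years gets the mean; otherwise the epoch nearest the median active
  year, ties toward 2009. The 1 km and 10 km radii are strongly
  collinear (r ≈ 0.8 in the motivating network) and are always fitted
  separately, selected by `analysis_config(hf_scale=)`.
* Standardization: footprint is z-scored across stations (sample SD),
  effort across station-years, and the year covariate is centered at the
  study midpoint with unit = one calendar year, so every trend
  coefficient is per-year on the link scale and $100(e^\beta - 1)$ is
  percent per year. The constants are stored in the fit so effects can be
  back-transformed to raw units. Standardization is a numerical choice of
  this package (the source analyses do not state one); it only rescales
  coefficients, and the per-year trend scale is unaffected.
* Filters: abundance uses stations with at least one capture;
  productivity additionally drops juvenile-only stations; survival needs
  at least 5 marked individuals per station. Individuals of unknown sex
  are excluded from the survival model with a logged count, since sex is
  a fixed covariate of all four probabilities.
* Effort enters as a standardized linear coefficient, not an offset,
  because the motivating analysis models it as an effect; a log-effort
  variant was considered and rejected as the default for the same reason.

## Inference

All coefficients get normal(0, variance $10^3$) priors (SD ≈ 31.6 on the
link scale); variances get inverse-gamma(0.001, 0.001). Sampling is
adaptive random-walk Metropolis-within-Gibbs: fixed effects update
single-site with proposal scales adapted toward ~0.35 acceptance during
burn-in only (the post-burn-in kernel is fixed, so the chain is valid);
station random effects and observation-level noise update as vectorized
elementwise Metropolis, which is exact because they are conditionally
independent given everything else; variance components are conjugate
inverse-gamma Gibbs draws. Initial values are N(0, 1) for coefficients,
zero for random effects and 1 for variances, all seed-controlled; a given
seed and configuration reproduce chains bit-for-bit.

The full protocol is two chains of 100,000 iterations, 80,000 burn-in,
thinned by 2 — exactly 20,000 pooled draws. The reduced preset
(2 × 4,000, 2,000 burn-in) is a first-class citizen used by the tests and
examples. Convergence is reported via Gelman-Rubin R-hat (identical
chains return $\sqrt{(n-1)/n}$, slightly below 1, by construction — the
degenerate zero-between-variance case) and intervals are 90% highest
posterior density, computed as the exact narrowest contiguous window of
sorted draws. No hard R-hat gate is imposed; values are reported and the
simulation-based calibration test guards the sampler itself (rank
statistics of the truth within the posterior are uniform on a reduced
model over 200 replicates).

## What the generator emulates — and what it does not

`simulate_banding_data()` produces the four tables (stations, counts,
productivity, capture histories) plus a ground-truth JSON sidecar from a
single seed. It draws a three-region network with coordinates consistent
with the region classifier, epoch footprints clipped to [0, 50] with the
two radii correlated, contiguous activity windows (about 8 active years
per station by default, matching a 59-station / ~480 station-year
network; full-span operation when `mean_active_years >= n_years`), effort
near 480 net-hours (a 6-9 day, 6-hour protocol), Poisson entries of newly
banded adults, Bernoulli(0.5) sex, and the exact generative structure of
the three models including station random effects drawn from their true
SDs. Default truths are the field-realistic values the models were built
around: survival near 0.31/0.45 (west female/male) with a 0.58 logit sex
effect, residency 0.58-0.67 in the west and 0.23-0.38 elsewhere,
recapture 0.27 (female) vs 0.56 (male), an eastern abundance decline near
-4.6%/yr, and juvenile proportions 0.32-0.43.

Deliberate simplifications: transients are permanently absent after their
first occasion (the standard transient-CJS convention); pre-determination
collapses the 6-9 within-season visits to one Bernoulli($\rho$) flag and
is possible only for residents, who are the only birds that can be
recaught within a season; recaptures are not suppressed in years a
station happened to be closed (the likelihood carries no station-operation
term, so generator and model agree); entries are not coupled to the
abundance surface; station placement is not spatially explicit and there
is no spatial autocorrelation (the motivating analysis dropped it too);
no climate covariates. A green recovery test therefore establishes that
the estimator recovers the generative structure it assumes — not that
real banding data satisfy that structure.

## Numerical choices and edge cases

* Linear predictors are clamped at ±30 (logit) and +300 (log) before
  exponentiation; a binomial cell with $p \to 1$ stays finite.
* A history with probability zero (e.g. a post-first detection under
  $\pi = 0$) yields `-Inf` log-likelihood, not an error; `NaN` terms
  raise an error naming the individual.
* One region is the reference (offset fixed at 0) for every
  region-structured survival/residency effect, since a common intercept
  plus a full set of region effects is over-parameterized.
* The survival trend covariate is evaluated at each interval's starting
  year; recapture probability is indexed to the occasion of potential
  recapture.
* Zero-variance covariates raise an error rather than producing NaN
  z-scores; zero-effort station-years are treated as not operated.
* `hpd_interval()` requires ≥ 100 draws; with mass 1 it returns the
  sample range. Ties in the narrowest-window search resolve to the
  leftmost window.

## Known limitations

Residency, recapture and survival are weakly separated when recaptures
are sparse: at ~1,500 marked individuals the likelihood ridge between
$\pi$ and $\rho$ is wide and posterior means of $\pi$ can sit several
hundredths from the truth in any one dataset, as the recovery tests'
replicate averaging acknowledges. The random-walk sampler is adequate at
these data sizes but slower-mixing than gradient-based samplers for the
high-dimensional noise layer. Counts are an uncorrected index; trends in
detectability masquerade as trends in density. The derived recruitment
inherits every assumption of both parent models, and includes adult
immigration by construction.
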