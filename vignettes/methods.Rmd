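---
title: "Methods: measuring temporal predictability in syllable-nucleus timing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring temporal predictability in syllable-nucleus timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(initempo)
```

## The problem

If the timing of syllables in running speech follows any pattern, a
listener — in particular an infant segmenting continuous speech — could
exploit it to predict where the next syllable nucleus will fall. This
package quantifies that predictability from manual point annotations of
syllable nuclei (the perceptual center of each syllable, where amplitude
peaks and harmonic structure is clearest), with phrase (`/`) and
sentence (`//`) break marks delimiting stretches of uninterrupted
rhythm.

The basic unit is the **inter-nucleus interval** (INI): for nuclei
$s = 1, \dots, n$ with times $t_s$ and intensities $a_s$ (dB),
$d_s = t_{s+1} - t_s$ and $i_s = a_{s+1} - a_s$. Intervals that span an
annotated break or an audio-part boundary are *masked*, not removed:
they become `NA` in place, so the series keeps its temporal alignment
and every downstream analysis handles the gap explicitly. A *rhythmic
phrase* is a maximal run of nuclei with no break between them; a
singleton phrase contributes no INIs but is still counted (the sources
this mirrors are silent on the convention; we fixed this one and use it
consistently).

All analysis happens on $\log d_s$: differences of logs are duration
*ratios*, which abstracts over speaking rate (a uniform time rescaling
leaves every log-ratio unchanged — a tested invariant). Natural logs
throughout; entropies are in nats.

## Order 0: distributional metrics

Two per-language descriptive statistics:

* `ks_normality_d(x)` — the Kolmogorov–Smirnov sup-distance between the
  empirical CDF of the INIs and a normal with the same mean and
  standard deviation, evaluated at both one-sided ECDF limits. It is a
  descriptive non-normality measure, so no Lilliefors correction and no
  p-value. Default input is raw INIs; log-INIs via the pipeline flag
  `ks_on_log` (the published table does not say which was used, so both
  are exposed). The matched sd uses the $n-1$ denominator by default,
  with `ddof` exposed.
* `npvi(d)` — the normalized pairwise variability index computed on
  INIs, $100 \cdot m^{-1}\sum |d_t - d_{t+1}| / \tfrac12 (d_t +
  d_{t+1})$ over the $m$ adjacent pairs in which **both** INIs are
  present. Dividing by valid pairs rather than $n-1$ is forced by the
  missing-value policy: pairs that span a break do not exist.

`dagostino_pearson()` implements the omnibus $K^2$ test (skewness
z-score after D'Agostino's transformation, kurtosis z-score after
Anscombe–Glynn), used to check that log-ratio distributions are
compatible with normality before the conjugate analysis below. It needs
$n \ge 8$; values were verified against an independent reference
implementation and frozen into the tests.

## Order 1: the Bayesian ideal learner

Let $r_s = \log d_{s+1} - \log d_s$ (defined only when both neighbours
are present). Assuming $r_i \sim \mathcal N(\mu, \sigma^2)$, the
learner carries a Normal-Inverse-$\chi^2$ conjugate prior with
$\kappa_0 = 0$, $\nu_0 = -1$, scale $0$ and arbitrary $\mu_0$ — the
uninformative setting in which the posterior depends on the data alone
and MAP estimates equal maximum likelihood ($\hat\mu = \bar r$,
$\hat\sigma^2 = \mathrm{ssd}/n$ with $\mathrm{ssd} = \sum (r_i - \bar
r)^2$; the unbiased $\mathrm{ssd}/(n-1)$ is also reported, ML is the
default variance column). $n$ counts present log-ratios pooled across
phrases.

The posterior predictive for the next interval is Student's t,
$t_{n-1}(\bar r, s)$ with squared scale
$s^2 = (1+n)\,\mathrm{ssd} / (n(n-1))$. We read the published scale
expression as the *squared* scale: it equals the standard
posterior-predictive variance factor $(1 + 1/n)\,\mathrm{ssd}/(n-1)$
of the conjugate model, and only that reading reproduces the published
entropy magnitudes. Predictability is summarized by the differential
entropy $h = -\int p \ln p$ (we use the conventional sign; lower = more
predictable), in closed form

$$h = \ln\!\big(\sqrt{\nu}\,B(\tfrac\nu2, \tfrac12)\big)
  + \tfrac{\nu+1}{2}\big(\psi(\tfrac{\nu+1}{2}) - \psi(\tfrac\nu2)\big)
  + \ln s,$$

checked against adaptive quadrature to 1e-8 and against the Gaussian
limit $\tfrac12\ln(2\pi e s^2)$. `sample_predictions()` implements the
generative account (draw $(\mu, \sigma^2)$ from the posterior, then
$r^{new}$ from the corresponding normal); its draws match the
closed-form t to KS distance < 0.01 at $10^5$ draws — the two routes
are kept separate deliberately so each can check the other.

## Higher order: ARMA multi-model inference

For each language the log-INI series (with `NA` gaps) is fit by every
ARMA$(p, d, q)$ variant with $p, q \in 0..5$ and $d \in \{0, 1\}$ — 72
variants — with the *preceding* intensity difference as an external
regressor ($x_t = i_{t-1}$, a basic stand-in for stress). $d = 1$
models relative durations (log-ratios), $d = 0$ absolute log
durations; $d > 1$ has no straightforward psychological reading and is
out of scope.

Numerical choices, all deterministic:

* Likelihoods are exact Gaussian, from the Kalman state-space
  recursion of `stats::arima(method = "ML")`, which skips missing
  observations. Differencing is applied *by this package* before the
  engine sees the series, for two reasons: `NA` propagation through
  the difference stays under our control, and the regressor must
  **not** be differenced — it already is a first-order intensity
  difference.
* Under $d = 1$ no drift term is fit by default (log-ratios are
  mean-zero to good approximation); under $d = 0$ an intercept is
  included. `include_drift` overrides.
* Observations whose regressor value is missing are masked (the
  likelihood cannot use them); masking never raises the effective
  sample size.
* $k$ counts every estimated parameter: $p + q$ coefficients, the
  intercept when present, the regressor coefficient when present, and
  the innovation variance. (A fixed always-count-the-intercept
  convention would miscount the default $d = 1$ fits.)
* $\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n_{\mathrm{eff}} - k - 1)$,
  infinite when $n_{\mathrm{eff}} \le k + 1$ (model excluded).
* Non-converged fits stay in the table with infinite AICc and zero
  weight, excluded from the weight normalization and logged — weights
  must compare actual maximized likelihoods.

Akaike weights are $w_i \propto \exp(-\tfrac12 (\mathrm{AICc}_i -
\min_j \mathrm{AICc}_j))$, normalized. The *Akaike set* is the minimal
prefix of the weight-sorted models reaching cumulative weight 0.95;
ties break toward smaller $k$, then smaller $p+d+q$, then lexicographic
$(p,d,q)$, so the set is well defined. Two summaries feed the report:
the percentage of weight on $d = 1$ (relative-duration) models, and
the weights marginalized over $d$ and $q$ for each AR order $p$.

## Inter-annotator agreement

`dtw_align()` is classic dynamic time warping over the
$|t_a - t_b|$ cost matrix with steps (1,0), (0,1), (1,1) and matched
endpoints, applied to nucleus events only (breaks are marks, not
timings). The path minimizes total absolute difference; the agreement
statistic is the *sum of squared* differences over the matched pairs —
following the two-step published description (cost metric $|\Delta t|$,
statistic $\Delta t^2$). `agreement_report()` computes
min(cross-group SSE) / max(same-group SSE) and passes at ratio ≥ 10.
Backtracking prefers the diagonal step on ties.

## The synthetic corpus: what it emulates and what it does not

`generate_corpus()` is the test stand-in for the annotated 18-language
narrative corpus. Its default profile takes, per language, the
published nucleus count (92–238), phrase count (11–41), median INI
(131–364 ms) and log-ratio variance (0.11–0.47), and generates iid
normal log-INIs with $\mathrm{sd}(\log d) = \sqrt{v/2}$ (for iid
log-INIs, $\mathrm{var}(r) = 2\,\mathrm{var}(\log d)$). Durations are
rescaled multiplicatively to hit the target median — an additive log
shift, so log-ratios are untouched and the recorded ground truth stays
exact. Breaks are placed between near-equal-length phrases (a jitter
option varies them; only phrase *counts* are published), inside gaps
larger than the largest INI so a masked interval can never be mistaken
for a real one. Intensities are Gaussian at 70 ± 4 dB — a typical
annotated conversational range, chosen once — with an optional
alternating stress offset and an optional coefficient feeding the
preceding intensity difference into the next log-INI (so exogenous
recovery can be tested against known truth). An `arima` process mode
generates AR/MA (optionally once-integrated) log-INIs for
parameter-recovery tests.

What a green synthetic test establishes: the estimators recover the
parameters of the stated generating processes at realistic sample
sizes. What it does not establish: anything about real speech —
synthetic data have no phonology, no speaker drift, no annotator bias,
and iid log-INIs are *more* regular than narrative speech between
breaks.

## Degenerate inputs and tolerances

Nucleus times live on a floating-point axis, so "all equal" INIs
reconstructed by differencing carry ~1e-16 jitter; variances below
1e-20 on the (dimensionless) log-ratio scale, or sds below 1e-10
relative to the mean duration, are treated as degenerate rather than
as vanishingly small entropy. A degenerate posterior flags entropy as
missing; the pipeline records the reason per field and continues.
Quantiles everywhere use the linear-interpolation convention (R type
7), which reproduces the published nucleus-count quartiles 159/177/190.

## Known limitations

* The ARMA stage inherits the usual volatility of order selection on
  short, gappy series; that is precisely why the report aggregates
  Akaike weights instead of trusting the single best model.
* Whether the published per-language fits re-included non-converged
  models, or used a drift under $d = 1$, is not recorded; our policies
  (exclude; no drift) are documented above and in the fit log.
* The TextGrid reader supports point tiers in both text forms but not
  interval tiers, audio, or embedded intensity (the tab-separated
  dialect carries intensities).
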