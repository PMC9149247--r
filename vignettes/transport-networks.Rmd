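---
title: "Inferring directed pollutant-transport networks with driftnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed pollutant-transport networks with driftnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftnet)
```

## The model

`driftnet` infers directed interaction relationships between pollutant
concentration series measured at many sites, on the premise that
atmospheric transport imprints a *temporal order*: if air carrying PM2.5
takes twelve hours to travel from city A to city B, B's concentration
series is, in part, a delayed and attenuated copy of A's.

The inference is deliberately two-staged.

**Stage 1 — lag-scanned cross-correlation.** For a city pair the package
computes the Pearson correlation profile

$$P(\tau) = \mathrm{Corr}\big(X_1(t),\, X_2(t - \tau)\big)$$

over an hourly lag grid, by default $\tau \in [-168, +168]$ h (one week
either way, the timescale on which synoptic weather systems move across a
region). Its maximum $P_{\max}$ measures the strength of a potential
relationship and the maximising lag $T_{\mathrm{delay}}$ its temporal
order. The sign convention follows directly from the definition: if
$X_2(t) = X_1(t - k)$ with $k > 0$ (the second city lags), the profile
peaks at $\tau = -k$, so a *negative* $T_{\mathrm{delay}}$ nominates
$X_1 \rightarrow X_2$.

Two tests gate each pair. First, a two-sided t-test that $P_{\max}$
differs from zero, $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of
freedom. Second, a one-sided Fisher r-to-z comparison that $P_{\max}$ is
significantly *larger* than the contemporaneous $P(0)$:

$$z = \frac{\operatorname{atanh}(P_{\max}) - \operatorname{atanh}(P(0))}
          {\sqrt{1/(n_{\max}-3) + 1/(n_0-3)}}$$

Without the second gate, a pair whose pollution simply co-varies (shared
regional weather, no transport asymmetry) would pass on the strength of
$P(0)$ alone.

**Stage 2 — Granger confirmation.** The candidate direction is then
tested with a bivariate Granger-causality F-test: the restricted model
predicts the target from $p$ of its own lags, the unrestricted model adds
$p$ lags of the source, and

$$F = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_u)/p}
          {\mathrm{RSS}_u/(T - 2p - 1)}$$

is referred to $F(p,\, T-2p-1)$. Both directions are always tested; an
edge is drawn only when the lag-nominated direction rejects. A rejection
only in the reverse direction is logged as an anomaly and produces no
edge — Granger is used here to *confirm* a direction proposed by the lag
scan, not to discover one. Running the two stages over all pairs within a
calendar month yields one directed, strength-weighted network per month.

### Assumptions

* Transport shows up as a lagged linear association; the Pearson/AR
  machinery sees neither nonlinear coupling nor time-varying lags within
  a window.
* Series are treated as (near-)stationary within a monthly window. Hourly
  PM within one month is usually close enough; a first-differencing
  switch (`difference = TRUE`) is available and its use is recorded in
  every result.
* Correlations are computed on raw concentrations — no detrending or
  deseasonalising — so a shared seasonal cycle can inflate $P(0)$ and
  $P_{\max}$ alike. The Fisher gate compares the two, which is exactly
  why it, and not the t-test, is the binding constraint in practice.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `tau_min`, `tau_max` | −168, +168 | h | one synoptic week either side |
| `step` | 1 | h | the measurement grid |
| `min_overlap` | 30 | hours (pairs) | below ~30 complete pairs a correlation estimate is too unstable to rank against 337 competitors |
| `alpha` | 0.05 | — | conventional; every gate takes it as an argument |
| `max_lag` | 24 | h | one day of autoregressive memory; transport lags beyond a day are attenuated past usefulness in hourly data |
| `criterion` | `"aic"` | — | standard order selection; `"bic"` and `"fixed"` available |
| `completeness_min` | 0.75 | fraction | a month missing more than a quarter of its hours cannot support a ±168 h scan at honest overlap counts |
| `multiplicity` | `"none"` | — | reproduces the uncorrected many-pairs analysis; `"bh"` offers a step-up correction of the Fisher-gate p-values |

## Design decisions in the open

Several choices had no single canonical answer; they are fixed as
follows and surfaced in results.

**Overlap counts with missing data.** Correlations use pairwise-complete
observations per lag; the $n$ supplied to each significance test is the
overlap count at the relevant lag ($n_{\max} = n(T_{\mathrm{delay}})$,
$n_0 = n(0)$). Missing hours are explicit gaps on the hourly grid and are
never imputed, at any stage.

**Fisher-test dependence.** $P_{\max}$ and $P(0)$ come from the same
data, while the z-test assumes independent samples. The dependent-case
correction needs the correlation between the two estimates, which is not
identifiable without resampling; the independent form is used, and its
anti-conservatism is part of why Stage 2 exists (see the calibration
note below).

**Argmax ties and boundary maxima.** Ties resolve to the smallest
$|\tau|$, then to the negative lag — deterministic, and preferring the
weakest (shortest-delay) claim. A maximum landing exactly on the grid
edge is flagged `boundary` and excluded from edges: an argmax at the edge
of the scanned window is not a located peak.

**$T_{\mathrm{delay}} = 0$.** The Fisher comparison is vacuous there
(it would compare $P_{\max}$ with itself), so a pair can be significant
at lag zero — but it yields no directed edge, because a contemporaneous
alignment carries no temporal order.

**Granger lag-order selection.** The order $p$ is chosen by AIC (or BIC)
on the *restricted* model — the target's own autoregression — not on the
unrestricted model that already contains the source lags. Selecting on
the unrestricted model picks whichever order most flatters the source
terms and then tests those same terms on the same data; in simulation at
$n = 744$ that inflated the empirical type-I error to ~0.12 at
$\alpha = 0.05$, versus ~0.05–0.07 for restricted-model selection with
indistinguishable power.

**Lag-order floor in confirmation.** When confirming a direction, the
order is selected over $|T_{\mathrm{delay}}| .. \texttt{max\_lag}$ rather
than $1 .. \texttt{max\_lag}$. The target's own AR structure is typically
short-memory, so unconstrained AIC picks a small $p$ — and an
unrestricted model whose lags stop short of the candidate transport delay
cannot see the relationship it is meant to test (on a 13-day window with
a true 12 h lag, unconstrained selection chose $p = 3$ and missed at
$p_F = 0.08$; at $p = 12$ the same data gave $p_F \approx 10^{-32}$).
The floor never applies to plain `granger_test()` calls, whose null
calibration is reported below.

**QC ordering.** Outlier, zero and duplicate removal happens per station
*before* cross-station averaging, so one corrupt monitor cannot
contaminate a city mean. Conflicting duplicates (same station and hour,
different values) are unresolvable and both copies are dropped, each
removal itemised so counts reconcile exactly with the input size.
Timestamps label the left edge of each hourly interval.

## What the simulator emulates — and what it does not

The synthetic scenario places cities on a plane, gives each calendar
month one wind vector, and lets an AR(1) plume (marginal mean 50, sd
25 µg/m³, coefficient 0.95) originate at the most-upwind city, arriving
at each downwind city after distance/speed hours, attenuated as
$e^{-\lambda d}$ ($\lambda = 5\times10^{-4}$ per km), on top of a
30 µg/m³ baseline and per-city AR(1) noise (sd 6, coefficient 0.8).
Station streams add iid noise (sd 2) and are then corrupted with the
pathologies real agency feeds show: dropped hours (2%), exact zeros,
duplicate records and >1000 µg/m³ outliers (0.2–0.4% each). With these
defaults the signal-to-noise ratio at the far end of the standard
5-city, 300 km-spaced chain is ≈ 2.3.

This tests the *statistics*, not the atmosphere: there is no dispersion,
chemistry, deposition, varying wind within a window, or curved
trajectory. Passing the recovery benchmarks therefore shows the
estimator correctly inverts lagged, attenuated, noisy common signals
under realistic data corruption — it does not validate the method
against real meteorology, which requires external wind or trajectory
data.

## Numerical and calibration notes

Problem sizes for the packaged validation runs were chosen to estimate
each rate to a usable precision: 500 replicates for the Granger null
(binomial se ≈ 0.01 at $\alpha = 0.05$), 200 for power and reverse-
direction rates, 20 seeds × 10 ordered pairs for the chain benchmark,
100 random instances for the brute-force oracle comparison (agreement to
≤ 10⁻¹²; observed ~10⁻¹⁶).

Measured behaviours worth knowing:

* **Granger stage**: type-I error ≈ 0.04–0.05 under independent AR(1)
  nulls at $n = 744$; power ≈ 1.0 against a lag-2 coupling of 0.6;
  reverse-direction rejections ≈ $\alpha$.
* **Two-test gate under pure white noise**: because $P_{\max}$ is the
  maximum over ~337 lags, its null expectation sits ~2 null standard
  errors above $P(0)$, and the one-sided Fisher gate passes far more
  often than $\alpha$ — measured ≈ 0.7 at $n = 744$. The gate does prune
  (the t-test alone passes ≈ 1.0), but pair-level selection is *not*
  $\alpha$-calibrated under the null; it is the Granger stage that
  controls false edges (0 false edges across the packaged null and chain
  benchmarks; per-pair false-edge probability ≈ rate × $\alpha$). Users
  wanting family-wise control across many pairs should switch
  `multiplicity = "bh"`.
* Degenerate inputs are defined away rather than crashed on: zero-
  variance slices make a lag undefined; $|r| = 1$ saturates the Fisher
  transform at $\operatorname{atanh}(1 - 10^{-15})$ with a warning and
  floors the t-test p-value at the smallest representable double.

## Limitations

* Bivariate only: a chain A→B→C will usually also show an A→C edge
  (truthfully — air does flow A to C); no conditional/multivariate
  Granger variant is offered to separate direct from mediated transport.
* The Fisher gate's independent-samples form is anti-conservative
  (above); do not interpret pair-level significance in isolation.
* Transport lags beyond `tau_max` are invisible, and beyond `max_lag`
  cannot be Granger-confirmed.
* Monthly windows assume the prevailing transport direction is stable
  within a month; a mid-month reversal averages into a weaker, possibly
  boundary-flagged peak.
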