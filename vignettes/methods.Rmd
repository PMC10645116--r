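---
title: "Methods: from radiocarbon dates to cooperation-driven growth waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from radiocarbon dates to cooperation-driven growth waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleowave)
```

`paleowave` reconstructs deep-time population dynamics from regional
radiocarbon date tables and asks a specific dynamical question of each
demographic expansion: did growth accelerate with population size (the
cooperative, Allee-type signature) before competition closed it down? This
vignette documents the statistical machinery, the choices made where the
methodology is genuinely open, and what the synthetic-data tests do and do
not establish.

## 1. The SPD as a population proxy

Each date is a conventional ¹⁴C age $y_m$ with lab error $\sigma_m$. Given
a calibration curve $(\mu(\theta), \sigma_c(\theta))$ mapping calendar year
$\theta$ (cal BP, 0 = AD 1950) to an expected ¹⁴C age, the calibrated
density at each integer year is the Gaussian ordinate

$$d(\theta) = \phi\big(y_m;\ \mu(\theta),\ \sigma_m^2 + \sigma_c(\theta)^2\big),$$

with the curve linearly interpolated to a 1-year grid. The SPD is the
pointwise sum of these densities over all dates. Two conventions matter:

* **Unnormalized densities (default).** Per-date densities are *not*
  rescaled to unit mass before summing. Rescaling concentrates mass
  wherever the calibration curve is steep and produces spurious spikes;
  raw ordinates avoid that artefact. Normalized mode is available (and is
  what the mass-conservation contracts test: each normalized date sums to
  1 within $10^{-6}$, an SPD of $n$ such dates to $n$ within $10^{-4}$).
* **Truncation at the window.** Mass falling outside the analysis window
  is dropped, never reflected or renormalized, so window edges do not
  distort interior values.

The proxy assumption — dated material accumulates in proportion to
population size — is taken as given, as in SPD-based demography generally.
Sampling effort, preservation and research bias all violate it in real
data; nothing in the pipeline corrects for them.

### Smoothing, trimming, generations

The annual SPD is smoothed with a **200-year centered rolling mean**
(even widths are rounded up to odd so the window centres exactly; edge
years without a full window are dropped rather than partially averaged).
Edges are then **trimmed**: leading/trailing years below $10^{-6}$ of the
series maximum are removed, since they reflect absence of data, not
population crashes. Smoothing runs before trimming so that the trim floor
is judged on the smoothed series; both the order's ingredients (floor,
bounds) are configurable. Finally annual values are **summed into 30-year
bins** — one human generation, the time step the growth models are
specified on. Summing (not averaging) captures the generational trend
while suppressing intra-generational variability; a partial trailing bin
is dropped, never zero-padded (padding would fabricate a crash). The bin
anchor is the oldest trimmed year by default and is exposed because the
phase of the 30-year grid is not otherwise determined.

## 2. Breakpoint detection

A demographic transition is located as a single structural change in the
series: every admissible split is tried, the chosen regression (segment
means by default; segment intercept-plus-slope as `trend_shift`) is fitted
independently to both segments, and the split minimizing combined RSS wins
— pre- and post-shift levels are estimated concurrently with the change
point. The search is exact (prefix-sum closed forms, verified against a
naive per-segment least-squares loop on every test series), runs on the
smoothed annual SPD by default (that is the series transition dates are
read off in practice; the generational bins are available via config), and
respects a minimum segment fraction of 0.15 per side — the usual
structural-change convention, since a "break" in the first or last few
percent of a series is indistinguishable from an edge artefact.

Numerical details: RSS values from prefix sums can go microscopically
negative by cancellation and are clamped at zero; a constant series is
reported as `sup_f = 0` with a `no_structural_change` flag (detected by a
relative threshold, $RSS_{null} \le 10^{-10}\sum y^2$) rather than as an
error; ties in RSS resolve to the earliest candidate.

Significance uses a **permutation test** by default: residuals from the
single-regime fit are permuted and the sup-F statistic recomputed,
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$, with $n_{perm} = 199$. This is
distribution-free but treats residuals as exchangeable — on a heavily
smoothed SPD they are strongly autocorrelated, so the p-value is
anti-conservative and should be read as a ranking device, not a calibrated
error rate. The alternative `asymptotic` mode is a Bonferroni-corrected
pointwise F tail bound over the candidates, conservative by construction.

## 3. Growth rates, waves, and the cooperation/competition model

With $X_t = \log SPD_t$ per generation, the log reproductive rate is
$R_t = X_{t+1} - X_t$, taken forward in time (decreasing cal BP). Bins
below a floor of $10^{-12}$ are clamped and flagged; any wave touching a
flagged bin is discarded, since a rate computed against the floor is an
artefact of the clamp. The floor exists because a trimmed SPD can still
contain interior stretches with essentially no dated material.

**Waves** are maximal runs of consecutive generations with
$R_t > 0$ (tolerance configurable; strictly positive is the default
reading of "uninterrupted growth", and a small negative tolerance admits
single near-zero dips). Waves with fewer than 4 points are kept but
flagged unfittable: the model below has 3 parameters, so 4 points is the
minimum leaving a residual degree of freedom.

The **reproduction curve** fitted to each wave is

$$R_t = R_m - c\,e^{X_t} - w\,e^{-X_t},$$

a Ricker map augmented with a hyperbolic cooperation term. $R_m$ is the
log maximum per-generation reproductive rate; $c \ge 0$ penalizes growth
per unit of population size (competition); $w \ge 0$ is the population
size scale cooperation requires (an Allee effect). Because the SPD stands
in for population size in arbitrary units, $c$ and $w$ are scale-dependent
and comparable only within a dataset; $R_m$ and the curve shape are
scale-free. Closed forms used throughout: peak at
$X^* = \tfrac12\log(w/c)$, $R^* = R_m - 2\sqrt{cw}$; equilibria are the
roots of $c x^2 - R_m x + w = 0$ (computed by the numerically stable
quadratic formula; degenerate cases $c = 0$ and/or $w = 0$ handled
analytically), with stability read from the map derivative
$|1 - c x^* + w/x^*| < 1$.

**Fitting.** The model is linear in $(R_m, c, w)$ given predictors $e^X$
and $e^{-X}$, so the closed-form least-squares solution exists; the
non-negativity constraints on $c$ and $w$ are handled exactly by
enumerating active sets (at most two bound constraints). `method = "nls"`
runs bounded Gauss–Newton from that start and is never allowed to report a
worse RSS than the exact linear optimum, which also guarantees the nesting
invariant $RSS_{full} \le RSS_{Ricker}$. On unconstrained problems the two
routes agree to $10^{-6}$ (asserted in tests). Constraints are on by
default — the parameters are intensities, negative values have no
interpretation — with unconstrained mode retained for diagnostics. A fit
with both constraints active is flagged degenerate.

**Model comparison.** The nested Ricker ($w = 0$) is fitted alongside and
compared by AIC with small-sample correction (AICc), appropriate at the
typical 8–15 points per wave; with $n \le k + 1$ the correction does not
exist and AICc is reported as `Inf`. A wave is classified `humped` when
both fitted $c$ and $w$ are strictly positive. No single "best explained"
verdict is issued: `shape`, `delta_aic`, $R^2$ and standard errors are
reported and the judgement is left to the analyst.

## 4. What the synthetic generator emulates — and what it does not

`cc_scenario()` builds datasets with exactly the statistical structure the
analysis assumes: a population trajectory iterated from the
cooperation/competition map through one or more parameter regimes
(switched to create abrupt transitions), multiplicative lognormal process
noise, calendar years of dated material drawn with probability
proportional to population size, and measured ¹⁴C ages equal to the curve
mean plus Gaussian noise with variance $\sigma_{lab}^2 + \sigma_c^2$.
Dates are independent draws — no site clustering, matching an analysis
that pools dates per region without site binning. There is no taphonomic
loss, no research bias, no spatial structure, and no reservoir effects:
passing the round-trip tests therefore shows the *pipeline* is correct and
well-calibrated under its own assumptions, not that real SPDs satisfy
those assumptions.

The reference scenario (`demo_scenario()`) holds a population at a low
Ricker equilibrium ($R_m = 0.3$, $c = 0.03$, size 10) for half of a
1000–9000 cal BP window, then switches to a cooperative regime ($R_m = 2$,
$c = 0.004$, $w = 0.8$, carrying capacity $\approx 500$), with process
noise 0.05 per generation, 5000 dates and a 25 ¹⁴C-yr lab error — values
typical of a data-rich regional Holocene compilation. The post-shift
regime is deliberately fast (the expansion completes within about two
generations): the recovery target for the breakpoint is the regime-switch
year, and the level-shift estimator inevitably centres on the expansion
ramp, so the ramp must be short for switch-year recovery to be a fair ask.
One subtlety is worth recording: the parameter change falls *between* two
generation points 30 years apart, and the series level can first respond
at the younger of the two. `scenario_truth()` therefore timestamps the
switch at the first generation governed by the new regime — on a
noiseless instant step the estimator then recovers it to the year.

A genuinely slow cooperative take-off (many generations of accelerating
growth) would be recovered as a humped wave just the same, but its
estimated break date would lag the parameter switch by the ramp length —
users comparing break dates to known events should keep that in mind.

## 5. Numerical conventions and test scale

* cal BP grids are stored ascending; forward in time always means
  decreasing cal BP. `break_cal_bp` is the first calendar year of the
  post-shift regime.
* Calibration requires the date to lie within the ¹⁴C span of its curve
  and the window within the curve's calendar support; a date merely
  incompatible with the window yields a zero density and a warning, not an
  error.
* All stochastic stages (simulation, date sampling, permutation test) are
  seeded; reports serialize deterministically, and rerunning a pipeline
  with identical inputs produces byte-identical JSON.
* Test problem sizes were chosen to exercise the estimators well inside a
  laptop-scale run: 500-series oracle sweeps for the breakpoint search,
  500-replicate recovery simulations at $n = 12$, $\sigma_R = 0.05$
  (median parameter errors a few percent), and a single 5000-date
  end-to-end scenario. The acceptance script reruns all of these from
  scratch at an arbitrary seed.

## 6. Known limitations

* Exactly one breakpoint is modelled; multi-break segmentation is out of
  scope, and a series with several comparable shifts will report only the
  dominant one.
* Marine/mixed calibration curves, reservoir offsets and Bayesian
  calibration are not implemented.
* The wave criterion (strictly positive 30-yr generational growth) is one
  consistent reading of "uninterrupted growth"; small changes to the
  tolerance or bin phase can split or merge borderline waves, so wave
  *counts* are less stable than wave *classifications*.
* The permutation p-value's exchangeability caveat above applies to every
  smoothed series.
* On real data, $c$ and $w$ inherit the SPD's arbitrary scale; only their
  signs, the curve shape, and scale-free summaries ($R_m$, peak location
  relative to the data) travel across regions.
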