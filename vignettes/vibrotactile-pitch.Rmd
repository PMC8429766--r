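---
title: "Vibrotactile pitch: the metamer model, its observers, and how the package validates them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibrotactile pitch: the metamer model, its observers, and how the package validates them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibropitch)
```

## The model

A sinusoidal substrate vibration is physically described by its frequency $f$
(Hz) and peak displacement amplitude $A$ (µm). Behavioural evidence from both
mouse forelimb and human fingertip experiments shows that the *perceived*
pitch of such a vibration is not a function of frequency alone: it behaves as
the product

$$\pi(A, f) = A^{k} \times f,$$

where $k$ is a dimensionless exponent that depends on where $f$ sits in the
species' vibrotactile spectrum. All $(A, f)$ pairs with equal $\pi$ are
perceptual *metamers*; they trace an equal-pitch curve in stimulus space. If
the amplitude is changed by a factor $N$, the frequency must be rescaled by
$(1/N)^k$ to keep the percept constant. The exponent is positive below the
frequency of highest vibrotactile sensitivity (about 1000 Hz in mouse, about
240 Hz in human) and negative above it, so equal-pitch curves always slope
toward the sensitivity peak.

`vibropitch` implements this model as pure functions (`pitch_value()`,
`equal_pitch_frequency()`, `equal_pitch_curve()`), the behavioural procedures
that measure it, the psychometric and power-law fitting stages that estimate
$k$, and generative observers that let all of it be validated by parameter
recovery on synthetic sessions. All pitch algebra is evaluated in log space so
extreme exponents cannot overflow; amplitudes are µm peak displacement and
frequencies Hz throughout, with dB meaning amplitude dB ($20\log_{10}$).

## The estimation chain

Perceptual reports are binary (lick / no lick; "first higher" / "second
higher"), so every experiment reduces to psychometric functions. The package
fits the cumulative Gaussian

$$\psi(x) = \gamma + (1 - \gamma - \lambda)\,\Phi\!\left(\frac{x - \mu}{\sigma}\right)$$

by direct maximum likelihood (`fit_psychometric()`), with the guess rate
$\gamma$ constrained equal to the lapse rate $\lambda$ in the default
equal-asymptote mode. The fitted $\mu$ is the point of subjective equality
(PSE). Fitting choices worth knowing:

* $\lambda, \gamma$ are bounded to $[0, 0.25]$ to prevent the classic
  asymptote/slope trade-off degeneracy.
* Optimisation is box-constrained (L-BFGS-B) from five deterministic starts
  (a probit-regression start plus shifted/widened variants), so fits carry no
  hidden randomness. The per-start results are kept in the fit's
  `convergence` report.
* $\mu$ is only accepted inside `[min level − 2·range, max level + 2·range]`.
  A fit whose $\mu$ lands *on* that boundary has a likelihood monotone in
  $\mu$ — the PSE is not identifiable from those data — and the pipeline
  treats it as a failed fit rather than a valid extreme estimate. This
  matters for the strongest amplitude probes, whose true PSE can lie beyond
  the sampled frequency range; accepting boundary-pinned values would bias
  the recovered exponent upward.
* CIs for $\mu$ come from a binomial (per-level) nonparametric bootstrap
  (`bootstrap_mu()`), deterministic given its seed.

With PSEs in hand, the exponent is estimated from the power law
$\mu/\mu_{\mathrm{REF}} = (A_{\mathrm{REF}}/A)^{k}$, i.e. from shift ratios
against amplitude change factors $\mathrm{ACF} = A/A_{\mathrm{REF}}$. Taking
logs makes this a straight line through the origin, so the primary estimator
in `fit_pitch_exponent()` is a no-intercept least-squares regression of
$\log(\mu/\mu_{\mathrm{REF}})$ on $-\log(\mathrm{ACF})$ — the only reading
under which a *linear* regression routine fits this power law. A nonlinear
least-squares estimate on the ratio scale is computed as a cross-check and
reported alongside; the two agree to $|\Delta k| < 0.01$ on clean data.
The 95% CI is $t$-based on the regression standard error, and the
significance rule sets the *effective* exponent to 0 whenever the CI includes
0 — non-significant fits are treated as "amplitude plays no role". Points at
$\mathrm{ACF} = 1$ carry a zero regressor and are excluded from the
regression. Mouse fits pool all animals' shift points; human fits use the
median shift ratio across subjects per ACF. Both conventions are exposed in
the result bundles.

## The generative observers

Published work specifies the *fitted description* of behaviour, not the
subjects' internal decision process, so the synthetic observers are an
explicit assumption layer (`observer_params()`):

* **Pitch.** The internal variable is $A^{k_{\mathrm{true}}} f$ with additive
  Gaussian noise *on the linear pitch axis* (SD `sigma_pitch`). This makes
  the go/no-go response function an exact cumulative Gaussian in frequency at
  each amplitude — matching the fitting model — and makes PSE ratios obey the
  power law exactly, which is what gives parameter recovery a well-defined
  truth.
* **Two-interval comparisons** difference two independent percepts, so
  comparison noise is $\sqrt{2}$ times single-interval noise — the standard
  signal-detection assumption; the task literature is silent on it.
* **Intensity.** Perceived intensity is modelled as amplitude re threshold,
  $A/T(f)$, with Gaussian noise on its log (SD `sigma_intensity`). This is a
  modelling choice, not an empirical claim: it makes simulated
  equal-intensity curves proportional to the sensitivity curve, with their
  minimum at the sensitivity peak, as observed.
* **Detection.** The probability of a correct 2AFC detection response is
  $0.5 + 0.5\,\Phi(20\log_{10}(A/T(f))/\sigma_{\mathrm{dB}})$ (lapse-scaled),
  i.e. 75% exactly at threshold. The generative threshold curve is
  log-quadratic, $T(f) = T_{\mathrm{best}} \exp(c\,(\ln f - \ln
  f_{\mathrm{best}})^2)$ — a V shape on log-log axes.
* Lapses are stimulus-independent random responses; the guess rate is the
  lower asymptote of the go/no-go response function.

### Default parameter values

The stimulus plans (frequency sets, amplitude sets, staircase tables, subject
counts) are the tested behavioural designs and live in `stimulus_plans()`,
mirrored by a checked-in JSON constants file the tests compare against.
Generative exponents default to the fitted behavioural values per spectral
location: mouse 0.32 (450 Hz), 0 (1000 Hz, where the fit is non-significant),
−0.044 (1600 Hz); human −0.24 (440 Hz). For the other human reference
frequencies only the sign of $k$ is established, so the defaults (+0.35,
+0.20, −0.10, −0.30 at 160, 200, 280, 480 Hz) are synthetic sign-consistent
choices.

Noise magnitudes were fixed once, at values that reproduce realistic
psychometric widths, and are not tuned per experiment: `sigma_pitch` gives
frequency-axis psychometric SDs of roughly 60–65 Hz for mice and ~9% of the
reference frequency (2AFC) for humans; `sigma_intensity` = 0.12 gives an
amplitude Weber fraction near 15%; detection noise is 3 dB (mouse) and 4 dB
(human); lapse/guess are 0.02 (mouse) and 0.03 (human), except the 1000 Hz
mouse range which uses guess 0.10 / lapse 0.05 and free-asymptote fits (that
range is the one where equal asymptotes cannot be assumed). V-curve
parameters are mouse (1000 Hz, 0.1 µm, curvature 1.6) and human (240 Hz,
0.2 µm, curvature 0.4), spanning ~35–45 dB across the tested range. Actuator
ceilings are modelled as $\min(10, 2000/f)$ µm (mouse) and $\min(40, 4000/f)$
µm (human), anchored to the reported extremes.

## Trial-selection machinery

* **Go/no-go scheduling** (`scheduler_params()`, `go_probability()`): either
  a gate requiring three consecutive correct rejections before a go trial, or
  the double sigmoidal bias-correction model
  $P_{go} = 1 - 0.5/(1 + (\frac{b+1}{\tau_1-1})^{S_1}) - 0.5/(1 +
  (\frac{b+1}{\tau_2-1})^{S_2})$ with $\tau_{1,2} = \mp 0.5$, $S_1 = 16$,
  $S_2 = 44$, where $b$ is the no-go-minus-go difference in fraction correct
  over the last 20 trials. The printed bases are negative; with even integer
  exponents this equals $|{\cdot}|^S$, and the implementation evaluates the
  magnitude so non-even exponents remain defined. When the window lacks one
  trial class entirely, that class's fraction is taken as 0. With fewer than
  20 trials the bias uses whatever the window holds.
* **Frequency staircase** (`freq_staircase()`): $\Delta$ starts at
  $\Delta_{\mathrm{MAX}}$ and moves down/up by $d\Delta$ after
  correct/incorrect answers; $d\Delta$ doubles after three successive
  same-direction changes and halves at each reversal, clipped to its per-plan
  bounds, with independent above/below tracks. Where the procedure is
  underspecified the package adopts one consistent convention: the step is
  applied with the *current* $d\Delta$ before any doubling/halving; the
  run counter resets after a doubling and on any reversal; $d\Delta$ starts
  at its minimum (starting at the maximum would make the doubling rule dead
  code); and $\Delta$ is floored at $d\Delta_{\min}$ so the test never equals
  the standard (a zero-difference trial has no correct answer).
* **3-down/1-up detection staircase** (`updown_staircase()`): 12 dB starting
  step, halved at each reversal with a 3 dB floor, stopping at five
  reversals; the threshold is the mean amplitude of the last 10 trials. The
  rule converges near the $0.5^{1/3} \approx 79.4\%$-correct point, and the
  test suite verifies that the median of 200 synthetic runs lands within 4 dB
  of that point computed in closed form.
* **Mouse bout procedure** (`bout_state()`): blocks of ≥ 12 trials holding
  ≥ 6 stimulus-present trials; > 70% correct attenuates the amplitude 4 dB,
  < 60% raises it 4 dB. The proportion is computed over *all* trials of the
  bout, and bouts are blocked (archive and restart), not sliding. The session
  threshold is the lowest amplitude with at least one bout beating chance in
  the exact one-sided binomial test at $\alpha = 0.05$; repeated sessions are
  averaged arithmetically in µm.

## What the synthetic data do and do not emulate

The generator reproduces the trial structures, adaptive dynamics, stimulus
plans and response statistics of the real tasks, which is what the fitting
chain is sensitive to. It does not model reaction times, learning or
motivation across sessions, serial dependencies beyond the schedulers' own
state, actuator nonlinearities, or any receptor mechanism linking the V-curve
to $k$. Passing recovery tests therefore show that *the analysis chain
recovers known truths from data with the paper-scale design and plausible
noise* — not that the observer model is the true generative process of mouse
or human behaviour.

## Numerical and design notes

* Equal-pitch algebra in log space; invariants hold to 1e−9 relative or
  better.
* The sum-of-exponentials equal-intensity fit $A = a e^{bf} + c e^{df}$ is
  ill-conditioned, so `fit_intensity_curve()` uses variable projection
  (exact linear solve for $a, c$ at fixed rates, Nelder-Mead multistart over
  $(b, d)$ across all sign patterns, rates capped so $|bf| \le 50$). The
  degenerate $b = d$ family collapses to a single exponential and is handled
  explicitly. Parameters are descriptive and not separately identifiable —
  the fitted *curve* is the output; bootstrap SDs (over subjects when a
  subject column is present) quantify its stability.
* Equal-intensity interpolation uses a natural cubic spline, exact at knots,
  with extrapolation refused.
* `aggregate_sensitivity()` reports the grid argmin of the mean threshold
  curve *and* an interpolated best frequency from the vertex of a quadratic
  fit in log-log coordinates. The human sensitivity peak (~240 Hz) falls
  between the tested 200 and 300 Hz, whose generative thresholds differ by
  under 0.3 dB — far below single-staircase noise — so only the interpolated
  estimate can resolve it.
* Every stochastic stage takes a seed; sessions, bootstraps and recovery
  studies are reproducible bit for bit. Sub-seeds are drawn per
  subject/session from the master seed.

## Problem sizes used in the validation suite

The recovery studies in the test suite and acceptance script run at the
behavioural designs' own scale: 4 mice × 5 probe sessions (450 Hz plan),
6 mice × 6 probe sessions (1600 Hz), 9 human subjects × 7 reference
amplitudes × 72 staircase trials (440 Hz), with 20 replicate experiments for
recovery medians and 50 for gate/argmin rates; detection uses 7 mice × 7
frequencies × 5 sessions and 19 humans × 14 frequencies. Unit tests use
smaller, clearly-labelled fixtures. The bootstrap-coverage check runs 60
replicate datasets of 99 resamples with a correspondingly widened binomial
band.

## Known limitations

* The exponent CI treats shift-ratio points as independent, but points from
  one subject share its $\mu_{\mathrm{REF}}$ estimate; the reference is
  estimated from several-fold more trials than each probe, so the induced
  correlation is small (gate calibration stays near its nominal 5% in the
  suite), but it is not zero.
* Exact numerical equality with toolbox psychometric fits (priors unknown) is
  not a goal; the MLE here is prior-free.
* PSEs far outside the sampled stimulus range are declared unidentifiable
  rather than extrapolated; with very noisy observers this can drop
  individual shift points (a warning is attached to the affected fits'
  absence in the bundles).
* The amplitude-comparison analysis maps PSEs through
  $\mu_{\mathrm{REF}}/\mu$, which carries a small Jensen-type upward bias at
  realistic noise; it is visible (a few percent) in the recovered
  equal-intensity points but does not move the curve's minimum.
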