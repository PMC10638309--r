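---
title: "Modelling response-selective stopping: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling response-selective stopping: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and algorithms in `sisstop`, the
assumptions they rest on, and the design choices made where the
literature leaves details open. The package addresses the
response-selective stop signal task: participants respond bimanually to
a go stimulus, and on a third of trials a later stop signal requires
cancelling one hand's response while the other continues.

## The SIS race model

The central model is the *simultaneously-inhibit-and-start* (SIS) race.
A selective stop signal is assumed to do two things at once: launch a
*dual-stop* process that races to inhibit the ongoing bimanual response,
and launch a fresh *unimanual* (selective) go process for the hand that
must continue. Four runners therefore exist: `dual_go` (launched at go
onset), `dual_stop`, and `sel_left` / `sel_right` (all launched at the
stop-signal delay, SSD). Each runner's finish time is ex-Gaussian with
parameters $\mu$, $\sigma$, $\tau$ (ms); its *running time* is
summarised by $\mu + \tau$, the distribution mean.

The race rule on a stop trial:

* with probability `gf` (go failure) the dual-go runner never launches;
* with probability `tf` (stop trigger failure) the stop signal goes
  unprocessed and *neither* the dual-stop nor the selective runner
  launches — the stop signal is treated as a single event that launches
  both, so one failure probability suppresses both;
* with probability `eps_wrong` the wrong hand's selective runner is
  triggered instead of the correct one;
* if the dual-go runner finishes before `SSD + t_stop` the trial is a
  failed stop (dual response at `t_go`); otherwise the trial resolves as
  a unimanual response at `SSD + t_sel`;
* any response falling after the 1100 ms deadline is recorded as no
  response; no renormalisation of observed-RT densities is applied.

On failed stops the selective runner is masked: the observed response is
the dual press at `t_go`, never a mixture of presses. Rare cells that
the mechanism does not generate (e.g. a unimanual response to a dual
stimulus) are absorbed by a per-trial likelihood floor
`p_floor = 1e-10`; these cells are empirically very rare and modelling
them mechanistically would add parameters the data cannot constrain.

The per-trial likelihood integrates the latent finish times analytically
except for the stop-versus-go race integral
$P_{\mathrm{win}}(d) = \int_0^\infty f_S(s)\, S_G(d+s)\, ds$,
which is evaluated by quadrature: adaptive quadrature (absolute
tolerance $10^{-6}$) in the exported `stop_win_probability()`, and
composite Gauss–Legendre (8 panels of 20 nodes over the stop runner's
effective support) inside the compiled likelihood used by the sampler.
The two routes agree to well below the adaptive tolerance and are
cross-checked against Monte-Carlo frequencies in the test suite.

Latencies are clocked from go onset and cannot be negative, so the
ex-Gaussian density is clamped to zero (and the survivor to one) at
$t \le 0$ without renormalisation; for every parameter range used here
the ex-Gaussian mass below zero is far below $10^{-10}$.

## Task design and the SSD staircase

Schedules reproduce the study structure: 576 trials per condition, one
third selective-stop trials split equally left/right, uniform 500–700 ms
foreperiods, an 1100 ms response window, and congruent "maybe stop
left/right" cues in the proactive condition. SSD is tracked by a
1-up/1-down staircase in 50 ms steps from a 200 ms start, independently
per condition and stop side. After a successful stop SSD *increases*
(the next stop signal comes later, making stopping harder); after a
failed stop it decreases. This negative feedback drives the long-run
success rate to 50%: over a long bounded run, up-moves and down-moves
must balance, so successes and failures occur equally often regardless
of the shape of the success-probability curve, provided the staircase
stays off its clamps. The clamps themselves are a design choice the task
description leaves open: floor 0 ms (negative delays are meaningless)
and ceiling `deadline − 100` ms (the stop signal must remain
displayable). Stop-trial order is a uniform shuffle within each
condition block; runs of consecutive stop trials are not constrained, as
no constraint is documented for the task.

## Hierarchical Bayesian estimation

`fit_sis()` estimates subject-level SIS parameters under independent
truncated-normal population distributions (a location and a scale per
parameter, no cross-parameter correlation). Go/stop/wrong-hand failure
probabilities are sampled on the probit scale, where the population
model is an untruncated normal in practice (support $[-6, 6]$).

Priors are weakly informative and cover the plausible human range with
wide mass: group locations $\mu \sim N(400, 200)$ on (1, 2000) ms,
$\sigma \sim N(50, 50)$ on (1, 500), $\tau \sim N(100, 100)$ on
(1, 1000), probit-scale $N(-1.5, 1)$ for the probabilities; group
scales get half-width truncated normals (e.g. $N(30, 30)$ on
(0.1, 300) for $\mu$).

Sampling is differential-evolution MCMC with at least $3k$ chains for
$k$ sampled parameters. Proposals are
$\theta^\ast = \theta + \gamma(\theta_a - \theta_b) + U(-\epsilon,
\epsilon)$ with $\gamma = 2.38/\sqrt{2k}$, occasionally $\gamma = 1$
for mode jumps, and $\epsilon = 10^{-3}$. Three refinements proved
necessary for mixing at this model size and are part of the design:

* group-level parameters are updated in per-parameter (location, scale)
  blocks rather than one joint move — a joint proposal across ~50
  hyper-parameters is essentially never accepted;
* each iteration adds a random runner-block refresh of the subject-level
  parameters on top of the full-vector crossover, which speeds mixing of
  weakly identified dimensions (notably the stop runner's $\sigma$);
* during burn-in, occasional migration moves let a random cycle of
  chains trade complete states, so stragglers can join the converged
  ensemble.

Fitting is two-stage: each participant is first fitted separately
(short DE-MCMC runs started from moment-based heuristics computed from
that participant's own response-time distributions), and those states
seed the hierarchical chains. Burn-in proceeds in windows with a
split-R-hat check on the group parameters after each window; once the
check passes (or a window cap is reached, which the fit object records
honestly), a fixed post-convergence window — 250 iterations per chain by
default — is retained for all analyses. The convergence *contract* is
what matters: all split-R-hat below 1.10 and effective sample sizes
above 200, both configurable; any sampler meeting it would be equally
acceptable.

Model variants 1/3/4/5 differ in which runners may vary by cueing
condition (the numbering convention of the original analysis code is
kept for traceability; "2" is deliberately absent). Variants are
compared by BPIC, $\bar D + 2 p_D$ with
$p_D = \bar D - D(\bar\theta)$ evaluated at the posterior mean of the
subject-level parameters. Contrasts of interest are computed on the
$\mu + \tau$ scale from individual-level estimates: per posterior draw,
subject values are averaged, the difference taken draw-wise, and the
draws summarised by median and central 95% interval. This aggregation —
subject-average first, contrast second — is stated explicitly because
reasonable alternatives exist (e.g. group-location contrasts); the
individual-level route matches how such contrast tables are normally
reported.

## EMG processing

Raw two-channel (bilateral FDI) signals at 2000 Hz are band-pass
filtered at 20–500 Hz with a 4th-order Butterworth filter, applied
forward–backward so that onsets are not delayed (zero phase; the filter
order is quoted before the direction doubling). Envelopes are full-wave
rectified signals low-pass filtered at 10 Hz, again zero-phase.

Burst detection uses a single threshold: the quietest 500 ms segment of
the rectified trace (minimum RMS, 1-sample stride, earliest window on
ties) provides the baseline, and the threshold is its mean + 3 SD —
applied to the *rectified* signal, a choice the source description
leaves open. Supra-threshold samples are clustered by merging gaps
shorter than 20 ms (band-limited activity dips below threshold at every
zero crossing, so merging is what makes a physiological burst one
event). Within a cluster the onset is refined to the first
supra-threshold sample followed by sustained activity (≥ 40% occupancy
over the next 10 ms), and the offset symmetrically; this stops an
isolated noise spike just before a burst from dragging its onset early,
and it is what makes noise-only traces yield exactly zero bursts.
Clusters shorter than 10 ms are discarded. Onsets and offsets have
0.5 ms resolution (one sample); burst peaks (time and amplitude) are
read from the envelope within the onset–offset span.

Classification follows the timing logic of the model. The RT-generating
burst of a hand is the *last* burst with onset after the go signal and
at least 50 ms before that hand's press. A partial (cancelled) burst is
the *earliest* burst satisfying four constraints: onset after go; peak
after SSD; peak before the responding hand's RT-burst onset; and peak
amplitude above 10% of the participant's mean successful bi-go envelope
peak, where envelopes are normalised to the mean peak over successful
*reactive* bi-go trials. Partial bursts are assessed in both hands but
only on successful stop trials. CancelTime is the partial-burst peak
minus SSD. Profile averaging aligns trials to go, stop, EMG onset or
peak, averages within participant and then across participants with
pointwise t-based 95% intervals.

## The censoring simulation

CancelTime can only be measured when a partial burst is *detectable*:
stopping must be slow enough to let muscle activity emerge but fast
enough that the cancelled burst separates from the RT-generating burst.
In model terms this is a window on the stop runner's winning margin
`t_go − (SSD + t_stop)`. The lower margin bound is the sum of three
latency components — partial-burst peak-to-offset (~50 ms), the
20 ms minimum gap the detector can resolve, and ~20 ms from RT-burst
onset to press (excluding electromechanical delay) — i.e. 90 ms; the
upper bound of 115 ms reproduces a realistic partial-burst prevalence.
(The bound that the field describes as the "upper threshold" on
stop-runner finish time is the *lower* bound on the margin; the package
names both on the margin scale to avoid the inversion.)
`censoring_bias_sim()` simulates staircased stop trials per condition
and compares the mean stop finish over all successful stops with the
margin-censored subset; under study-scale parameters the censored mean
is lower — a down-bias — which is the model-based explanation for small
condition differences in CancelTime arising without any true difference
in stopping speed.

## The synthetic-data generator

`group_truth()` fixes the study conditions the generator emulates:
reactive dual-go running time 450 ms, slowed to 480 ms by proactive
cues (+30 ms); a condition-invariant dual-stop runner at 200 ms;
selective runners at 316 ms reactive / 289 ms proactive (matching
typical relative RTs); go-failure 2%, trigger-failure 5%, wrong-hand
1%; between-subject SDs of 20/8/10 ms on $\mu/\sigma/\tau$ and 0.15 on
the probit scale. `generate_behaviour()` runs every subject through
both 576-trial conditions with live staircases, adding a Gaussian
bimanual press asynchrony (SD 25 ms, giving the familiar ~4–5% of
dual presses separated by more than 50 ms) so simultaneity cleaning has
realistic work. Seeds split per cohort, subject and condition, so any
subject's block is independently reproducible.

`synth_emg()` ties raw EMG to the latent race: pressing hands get
RT-generating bursts starting one electromechanical offset (60 ms,
comfortably above the 50 ms detection constraint) before the press;
successful stops whose margin falls in the 90–115 ms detectability
window get partial bursts peaking exactly at `SSD + t_stop`. Bursts are
band-limited (20–500 Hz) noise under smooth amplitude windows on a
Gaussian noise floor, at SNR 10 by default. Two morphology choices
matter and are deliberate: RT bursts rise fast (6 ms) so raw threshold
crossings pin their true onsets, while partial bursts use a symmetric
raised-cosine window so the 10 Hz envelope peak is an unbiased read-out
of the planted CancelTime. Partial bursts are planted at half the
RT-burst amplitude (single-trial recordings show cancelled bursts at
roughly this scale; no tabulated value exists to adopt). Partials are
only planted where the model's own classification constraints could
ever accept them — in particular not when the planted peak would fall
after the responding hand's RT-burst onset, and not in the responding
hand when the burst would collide with the RT burst (offset within
~20 ms of its onset) — because such activity would not exist as a
separate burst; this is what makes round-trip sensitivity a meaningful
detector property rather than a tautology.

What the generator does *not* emulate: motor-unit physiology, tonic
pre-stimulus activity, electrode artefacts, drifts, or mirror activity
(unless explicitly planted for stress tests). Passing round-trip tests
therefore show that the pipeline recovers what the model says should be
there; they do not certify performance on real recordings.

## Numerical and scale choices

* Quadrature tolerances: $10^{-6}$ absolute for race integrals; cell
  probabilities sum to 1 within $10^{-4}$ and are verified against
  $10^5$-trial Monte-Carlo frequencies within three binomial SEs.
* Strict inequalities resolve all boundary rules (25% exclusion, 50 ms
  simultaneity, 100 ms fast-guess flag), matching their printed forms.
* Test and example problem sizes are deliberately desk-scale: recovery
  uses 8 synthetic subjects with 288 trials per condition and reduced
  sampler settings (about 10 minutes on one core); model-selection
  consistency uses 3 replicate cohorts of 4 subjects at variant-1 truth
  and checks that BPIC prefers variant 1 over variant 5 in the
  majority. Headline numbers from a 36-participant human study are not
  reproducible at this scale and are not targets of the test suite.
* The staircase direction follows the tracking logic that makes ~50%
  success rates and above-start mean SSDs possible (increase after
  success); descriptions that state the opposite direction are
  internally inconsistent with those outcomes.

## Known limitations

* The wrong-hand mechanism (`eps_wrong`) and the likelihood floor are
  deliberately coarse; cells like "left response to dual stimulus" are
  not modelled mechanistically.
* The group model has no cross-parameter correlations; real populations
  likely correlate $\mu$ and $\tau$.
* At desk scale the sampler's split-R-hat can remain above threshold for
  weakly identified subject-level parameters (the stop runner's
  $\sigma$) even when group-level running times are stable; the fit
  object reports this honestly rather than masking it.
* EMG onset accuracy (±5 ms at SNR ≥ 8) assumes bursts with fast rises;
  slowly recruiting activity will be detected late by any threshold
  method.
* Single-trial CancelTime carries a few milliseconds of localisation
  jitter: rectified-noise fluctuation surviving the 10 Hz envelope
  low-pass shifts the argmax of a ~100 ms hump by up to ±8 ms on
  occasional trials. CancelTime is accurate to within ±5 ms *on
  average*; per-trial values should be treated as noisy measurements,
  which is how the derived summaries use them.
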