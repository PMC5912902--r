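---
title: "Closed-loop stimulation and decision thresholds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop stimulation and decision thresholds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`adbsddm` simulates and analyses an experiment in which subthalamic
deep-brain stimulation (DBS) is delivered in closed loop — triggered by
beta-band (13–30 Hz) amplitude of the subthalamic local field potential —
while a patient performs a moving-dots decision task with speed/accuracy
instructions and two motion coherences.  Because beta fluctuates, adaptive
stimulation hits different trials at different times, which turns a
clinical stimulation regime into a temporally specific perturbation probe:
one can ask *when* stimulation must arrive to alter a latent
decision-making parameter.  The package provides every stage as tested
code on synthetic data with known ground truth: a cohort generator, the
closed-loop controller, sliding-window behavioural contrasts with
cluster-based permutation correction, Morlet-wavelet beta metrics, and
hierarchical Bayesian drift-diffusion regression.

## The decision model

Behaviour is modelled as a drift-diffusion process: noisy evidence
accumulates at drift rate $v$ (units of evidence/s) from a neutral start
point ($z = 0.5$, both responses equally likely) until it reaches one of
two boundaries separated by the decision threshold $a$; the response time
adds a non-decision time $t$ for afferent and motor delays.  The diffusion
scale is fixed at $s = 1$, so all parameters are in that convention.  The
likelihood is the Wiener first-passage-time (WFPT) density, computed with
an adaptive switch between the small-time and large-time series
expansions; the truncation bound is chosen per evaluation so the error is
below `tol` (default $10^{-7}$ — the dominant cost of a fit is MCMC, not
density calls).  Two closed forms anchor the implementation in tests: the
absorption probability at the upper boundary,
$(1 - e^{-2vaz})/(1 - e^{-2va})$, and the symmetric-start mean decision
time $(a/2v)\tanh(va/2)$.

Trial-wise regression designs place experimental covariates on the three
parameters.  The named variants are

* **M1** `a ~ Instr + Coh`, `v ~ Coh` — the baseline task model;
* **M2** the 9-coefficient stimulation-interaction model
  (`a ~ Instr + Coh + Stim + Instr:Stim + Coh:Stim`,
  `v ~ Coh + Stim + Coh:Stim`, `t ~ Stim`);
* **M3** the post-hoc split `a ~ Instr + Coh_Stim + Coh_noStim + Stim`,
  `v ~ Coh`, where `Coh_Stim`/`Coh_noStim` separate the
  coherence–threshold increment by whether the trial received effective
  stimulation 400–500 ms post-cue;
* **M4** = M3 with `Stim` marking the continuous-stimulation session;
* **M5/M6** add z-scored single-trial beta metrics (cue-induced decrease;
  late 500–800 ms power split by coherence) as threshold regressors.

Subjects are partially pooled: $v_s, a_s, t_s$ are drawn from group
distributions with means $\mu_v, \mu_a, \mu_t$ and SDs
$\sigma_v, \sigma_a, \sigma_t$; regression coefficients are estimated at
the group level only, which regularizes trial-wise designs and avoids
parameter explosion.  Priors are weakly informative and overridable
(`ddm_priors()`): $\mu_a \sim N(1.5, 0.75^2)$ truncated positive,
$\mu_v \sim N(2, 3^2)$, $\mu_t \sim N(0.4, 0.2^2)$ truncated
non-negative, half-normal group SDs (scale 1, 1, 0.3) and $N(0, 2^2)$
coefficients.  The exact priors of the original modelling framework are
not published; these defaults are deliberately explicit instead.

Sampling uses single-site adaptive random-walk Metropolis implemented in
C++ (proposal scales adapt during burn-in toward 44% acceptance;
hyperparameters see only the subject-level prior terms, subject
parameters only their own trial block, coefficients the full data).
Convergence is monitored with the Gelman–Rubin statistic over at least
two chains from jittered starts; fits warn when any R-hat is 1.1 or
above.  Model evidence uses the classical DIC
($\hat D + 2p_D$, $p_D = \bar D - \hat D$); hypothesis tests are
posterior probabilities with the 0.95 decision rule, and model adequacy
is checked with quantile-probability summaries (RT percentiles 10–90
against percentile × response probability, with the predictive spread
over replicated datasets).

## The closed-loop controller

The device chain is emulated as: band-pass filter within the 3–37 Hz
analog passband around the beta peak, rectification, and a 400 ms causal
moving average (`beta_envelope()`).  The trigger turns ON when the
smoothed envelope is at or above threshold — the envelope median, which
yields a trigger duty near 50% on stationary input — and OFF when it
falls below.  Voltage ramps linearly over 250 ms in both directions (the
ramp shape is not specified by the hardware description; linear is the
package's choice, exposed in the configuration), and a 500 ms lockout
after each trigger-off blocks re-triggering; because the lockout exceeds
the ramp, every ON episode starts from zero voltage.  Only full-voltage
samples count as clinically effective stimulation
(`effective_stim_mask()`), so each episode loses its first 250 ms, and
episodes shorter than the ramp deliver nothing.  Surrogate stimulation
applies the same thresholding to an off-stimulation envelope at the
patient's realized trigger duty and removes each episode's first 250 ms —
the control for beta fluctuations without stimulation.  The controller
runs at the envelope rate (200 Hz, the offline analysis rate; the online
rate of the hardware is unstated).  Bilateral control would be two
independent instances with per-trial flags OR-ed across hemispheres; the
synthetic cohort models one effective channel per patient, matching the
averaged-hemispheres analysis path.

## The synthetic cohort

The generator is first-class, tested code; its defaults define the study
conditions: 7 patients × 3 sessions (off, continuous, adaptive) × 240
trials (12 alternating 20-trial instruction blocks, equiprobable
unpredictable coherence, pre-cue jitter uniform on 0.75–1.25 s).

**Behaviour.** Per-trial thresholds are
$a_k = a_s + b^{instr} \mathrm{Instr}_k + b^{coh} \mathrm{Coh}_k + \eta_k$
with trial noise $\eta_k \sim N(0, \sigma_\eta^2)$, and drifts
$v_k = v_s + b^{cohv}\mathrm{Coh}_k$.  In trials flagged as effectively
stimulated 400–500 ms post-cue, the coherence–threshold increment is
removed — the generative encoding of the timing-specific stimulation
effect, which makes recovery testable.  Defaults
($\mu_a = 1.5, \mu_v = 3.2, \mu_t = 0.35$, $b^{instr} = -0.6$,
$b^{coh} = 0.8$, $b^{cohv} = -2.5$) were calibrated once against the
reference behaviour: accuracy ≈ 80%/97% in low/high coherence, a median
instruction speeding of ≈ 0.14 s, omissions below 2% at the 3 s deadline,
and a median coherence slowing of ≈ 0.49 s.  The reference slowing of
0.68 s is not attainable jointly with < 2% omissions under a pure
three-parameter DDM — the first-passage tail scales with the median, and
0.68 s of slowing implies roughly 4% of low-coherence trials missing the
deadline — so the calibration favours the omission constraint; all effect
*directions* and accuracy levels match.

**Beta envelope.** A burst-like baseline (exponentiated
Ornstein–Uhlenbeck log-amplitude, correlation time 400 ms, log-SD 0.3 —
free parameters, since burst statistics of the patients' envelopes are
not reported) is modulated multiplicatively per trial: a cue-locked
linear decrease over 150–400 ms whose depth is larger after speed
instructions and (weakly) smaller in high-threshold trials; a post-trough
rebound to a fixed recovery level; in low-coherence trials a relative
increase 500–800 ms whose amplitude is linearly coupled to the trial's
threshold deviation $\eta_k$; in high-coherence trials a continued
decrease; and a brief motor-execution beta decrease beginning 200 ms
after the keypress, with its onset additionally gated past the late
analysis window (see the caution below).  A sinusoidal carrier at the subject's beta peak frequency
plus white noise gives a synthetic raw LFP for the wavelet chain.  Two
timing choices matter and are deliberate: the rebound level is *fixed*
(not tied to the trial's cue-drop depth) and the execution dip *follows*
the response.  Both are physiologically standard (post-trough beta
rebound; movement-related desynchronization during execution), and they
are what makes the generator internally consistent: with them, a zero
coupling coefficient really does produce a late-beta metric that is
uncorrelated with the trial's threshold, which the null-recovery tests
require.  An earlier parameterization in which the window inherited the
cue-drop floor and the dip preceded the keypress leaked
threshold-unrelated RT structure into the 500–800 ms window; the methods
below explain why such leaks are poisonous.

**Closed loop.** For adaptive sessions the controller runs on the
smoothed envelope of a provisional stimulation-free pass (threshold = the
session median, approximating the rest-period calibration); the resulting
effective-stimulation flags feed back into behaviour, and envelope and
trace are regenerated with the same noise streams.  Trial slots have
fixed length (jitter + 3 s deadline + 0.5 s feedback), so cue times do
not depend on realized RTs and the envelope before 500 ms post-cue is
identical across passes — the flags are therefore exactly the flags of
the final session.  Continuous stimulation is an all-ON effective mask
(every trial stimulated); off is all-OFF.

## Sliding-window contrasts and cluster inference

Effective stimulation is labelled per trial in 100 ms windows stepped by
10 ms (half-open `[start, start + width)`; the edge convention is the
package's choice), spanning 0 to +1 s around the cue and −1 to 0 s around
the response — 91 windows per alignment.  Per patient and window, the
stimulation effect on a factor is the double difference of median RTs,
e.g. (low−high | stim) − (low−high | no-stim); windows with an empty cell
are missing for that patient, windows with fewer than 4 contributing
patients are excluded, and an all-ON mask (continuous stimulation) raises
an explicit error rather than returning zeros.  Across patients each
window gets a one-sample statistic; the default is the *z*-like
mean/(SD/√n), for which the threshold 2.24 = Φ⁻¹(1 − 0.05/4) (correcting
for the four sliding-window analyses) has its nominal meaning — a raw
mean/SD variant is available (`stat = "mean_sd"`), but with seven
patients its null rarely exceeds 2.24 and the procedure would be far more
conservative than the stated α.  Maximal contiguous supra-threshold runs
form clusters scored by mass (sum of |z|; size by option — "larger than"
is ambiguous between the two, mass is the package's choice), compared
against the permutation distribution of the maximum cluster mass under
within-patient label exchange (sign flips of each patient's contrast),
with significance at the 95th percentile.

One scope limit deserves emphasis.  The permutation test assumes the
stimulation labels are exchangeable under the null.  For *cue-aligned*
windows on this generator that holds to good approximation and the
family-wise error calibrates near its nominal level.  For
*response-aligned* windows it does not: the labels derive from an
envelope whose structure is locked to the cue, and mapping fixed
post-cue features into response-relative coordinates makes the labels
depend on each trial's RT — the very outcome being contrasted.  On null
cohorts the response-aligned coherence contrast then produces spurious
clusters at far above the nominal rate.  This is a property of
closed-loop designs, not a bug in the test: stimulation timing is
outcome-entangled by construction.  The package therefore treats
response-aligned cluster results as descriptive diagnostics; calibrated
inference is claimed for the cue-aligned analyses only.

## Beta-power metrics

Time-frequency power uses Morlet wavelets at 3–30 Hz in 1 Hz steps with
the linear cycle rule cycles(f) = 2 + 3(f−3)/27, amplitude-normalized so
a unit sinusoid gives unit power, edges flagged invalid within one
wavelet half-length, and per-frequency normalization to the
experiment-wide mean (so normalized power has mean 1 at every frequency).
Condition averages cap each trial at its response and extend to the
condition's median RT (the 50%-inclusion point).  The cue-induced
decrease is power(100–150 ms) − power(trough ± 100 ms), with the trough
latency estimated once per subject from the average trace within
300–500 ms and applied to every trial (a per-trial trough search would
capture noise minima).  Late beta is the window mean over 500–800 ms,
z-scored within subject separately per coherence.

**A caution that shaped the design.**  In a trial-wise DDM regression the
only channel carrying information about a trial's threshold is that
trial's RT (and accuracy).  Consequently (i) any regressor component that
co-varies with RT for *non-threshold* reasons — such as a motor-execution
beta decrease reaching into the analysis window on fast trials — is
indistinguishable from threshold coupling and inflates the coefficient
even when the true coupling is zero; (ii) *removing* the RT-correlated
part of the regressor (RT-orthogonalization) removes the signal as well,
driving every coefficient to zero; and (iii) excluding trials by an RT
cutoff makes the regressor's availability depend on the outcome noise, a
collider that biases the coefficient toward zero or below — measurably:
with a cutoff at 800 ms, even a *perfect* regressor (the generative
$\eta_k$ itself) recovers only a third of the true slope on this
generator.  Measured on intermediate generator designs, even a mild
in-window dip left the zero-coupling null mildly inflated (coefficient
≈ +0.03, crossing the 0.95 probability rule in a large minority of
seeds).  The package therefore keeps the plain 500–800 ms metric as the
default analysis path and gates the generator's execution dip past the
late window, so that in-window beta carries *no* response-time structure
by construction and the zero-coupling null is exact.  This is a
deliberate property of the synthetic ground truth, not a claim about
real recordings: on real data the motor decrease of fast trials does
reach such windows, the confound is live, and none of the package's
passing tests certify otherwise.  `exclude_short` (fast-trial exclusion,
implemented as regressor-zeroing so the likelihood is never truncated)
and `detrend_rt` are exposed as robustness options whose costs are
exactly the ones itemized above.

## Cohort statistics

Signed-rank tests are implemented directly so that the normal-approximation
*Z* is available (zero differences dropped, midranks, continuity
correction), with exact enumeration of all 2ⁿ sign patterns for n ≤ 12
without ties; `stats::wilcox.test` serves as an independent oracle in the
tests.  Identical paired vectors return Z = 0, p = 1 with a warning
rather than an error, so degenerate null cases remain usable.  Condition
effects are compared as percent change, (effect_on − effect_off) /
effect_off × 100, controlling for overall RT changes.  Correlational
hypotheses use within-subject Spearman coefficients, Fisher-z
transformed, tested against zero across subjects with the signed-rank
test.  The design-stage sample-size computation follows the
asymptotic-relative-efficiency method: a signed-rank test on n pairs from
a normal parent has the power of a paired t-test on 3n/π effective pairs,
evaluated with the noncentral t distribution (fractional degrees of
freedom allowed); dz = 1.75 at α = 0.05 and 90% power gives n = 6.

## Numerical choices and problem sizes

Forward simulation uses Euler–Maruyama; the likelihood-validation tests
use dt = 1e−4 s, the cohort generator dt = 2e−4 s (its own calibration
was run at that step, so generation is self-consistent; the small
discretization bias is absorbed into the calibrated defaults).  The test
suite runs scaled-down replications chosen to be statistically meaningful
on one CPU: recovery sweeps use 20 cohorts at 800–1000 kept draws × 2
chains, the family-wise-error calibration 200 null cohorts with
100-permutation cluster tests, and the power property 10 cohorts.  The
methodological claims do not depend on these sizes; rerunning with larger
settings only narrows the Monte-Carlo error.

## Known limitations

The generator emulates the *statistical structure* the analyses assume —
not raw broadband LFP (no 1/f background, no stimulation artifacts, no
theta band), not paraesthesia or other side effects, and no
response-terminated trial timing.  Passing tests demonstrate that the
pipeline recovers known ground truth under this structure; they cannot
certify behaviour on real recordings with artifact structure the
generator lacks.  The coherence-slowing magnitude is compressed relative
to the reference behaviour (see above).  Omission handling, the 0.25 s
fast-RT cutoff, and the fixed 0.5 start point follow the reference
analysis; inter-trial variability parameters (sv, sz, st) are
deliberately absent from the fitted models, and the generator's
trial-wise threshold noise is therefore unmodelled variance during
fitting — a realistic misspecification that the recovery tests span.
Whether the non-decision time should carry a stimulation regressor
outside M2 is treated as stated (it does not); a sensitivity analysis is
a one-line model change via `ddm_spec()`.
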