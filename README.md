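# adbsddm

Simulation and analysis of **closed-loop (adaptive) deep-brain
stimulation during perceptual decision making**, for computational
neuroscientists and methodologists who want the full analysis chain —
from a beta-triggered stimulation controller to hierarchical Bayesian
drift-diffusion regression — as tested, reproducible code on synthetic
cohorts with known ground truth.

The scientific setting: patients with subthalamic DBS electrodes perform
a moving-dots task (speed vs accuracy instructions × 8%/50% motion
coherence) in three sessions — stimulation off, continuous 130 Hz
stimulation, and adaptive stimulation in which 130 Hz bursts are
triggered whenever the subthalamic beta-band (13–30 Hz) amplitude
envelope exceeds its median, with 250 ms voltage ramps and a 500 ms
lockout.  Because beta fluctuates, adaptive stimulation hits different
trials at different times; sliding-window contrasts with cluster-based
permutation correction locate *when* stimulation changes behaviour, and
drift-diffusion models with trial-wise regressors identify *which*
latent parameter it moves.

## The model at the core

Choices and response times follow a drift-diffusion process: evidence
accumulates at drift rate *v* from an unbiased start (*z* = 0.5) to
boundaries separated by the decision threshold *a*, plus non-decision
time *t* (diffusion scale *s* = 1).  The likelihood is the Wiener
first-passage-time density with adaptive small-/large-time series
expansions.  Hierarchical fits pool subjects
(v_s, a_s, t_s ~ group distributions) and place trial-wise regressors on
the parameters, e.g. the baseline model

    a_{s,k} = a_s + b1 Instr_k + b2 Coh_k        v_{s,k} = v_s + b3 Coh_k

and the stimulation split

    a_{s,k} = a_s + b1 Instr_k + b2 Coh_Stim_{s,k} + b3 Coh_noStim_{s,k} + b4 Stim_{s,k}

which separates the difficulty-related threshold increase by whether the
trial received effective stimulation 400–500 ms post-cue.  Inference is
MCMC (adaptive Metropolis in C++), hypothesis tests are posterior
probabilities with a 0.95 decision rule, model comparison is DIC,
convergence is Gelman–Rubin R-hat, and model adequacy is checked with
quantile-probability summaries.

## Worked example

```r
library(adbsddm)

# one patient's adaptive-stimulation session with ground truth
ses <- generate_session("adbs", seed = 3)
ses$stim
#> Stim trace: 217248 samples at 200 Hz, trigger duty 46.6%, effective duty 35.5%
mean(ses$trials$stim)          # trials hit 400-500 ms post-cue
#> [1] 0.4166667

# a full cohort (7 patients x off/cDBS/aDBS x 240 trials) and the
# threshold-split model on the adaptive sessions
coh <- generate_cohort(seed = 101, keep_sessions = FALSE)
nrow(coh$trials)
#> [1] 5040
fit <- fit_ddm(build_model(coh$trials[coh$trials$condition == "adbs", ], "M3"),
               n_draws = 1000, n_burn = 1000, seed = 5)
posterior_probability(get_draws(fit, "a_Coh_noStim"))  # low > high, no stim
#> [1] 1
posterior_probability(get_draws(fit, "a_Coh_Stim"))    # low > high, stim
#> [1] 0.895
```

Read: without stimulation in the 400–500 ms window the decision
threshold is credibly higher in difficult (low-coherence) trials
(posterior probability 1.00); in trials stimulated in that window the
increase is gone (0.90, not significant at the 0.95 rule) — the
generator injected exactly this pattern, and the model recovers it.

The sliding-window analysis on the same cohort finds the corresponding
behavioural cluster:

```r
coh <- generate_cohort(seed = 1, conditions = "adbs")
lab <- cohort_window_labels(coh)
eff <- stim_contrast(lab$cue$trials, lab$cue$labels, "coherence")
cl <- cluster_permutation(eff, z_thresh = 2.24, n_perm = 1000, seed = 1)
cl[1, ]
#> # A tibble: 1 x 5
#>   start   end  mass p_value significant
#> 1     1    84  829.  0.0170 TRUE
range(attr(cl, "z")[41:46])      # windows starting 400-450 ms
#> [1] -51.8 -23.2
```

The per-window statistic peaks at −52 in the windows overlapping the
injected 400–500 ms effect and decays to −2…−6 elsewhere; the cluster
nevertheless spans most of the first second because closed-loop
stimulation labels are correlated across windows (a high-beta trial
tends to be stimulated throughout), which keeps distant windows mildly
supra-threshold and contiguous.  `run_pipeline(pipeline_config(seed = 1))` chains
all stages (generate → controller → windows → fits → statistics) into a
run directory with CSV tables, a log of every seed and threshold, and a
markdown report.  A thin command-line front end with the same stages is
in `exec/adbsddm`.

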