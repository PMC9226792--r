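---
title: "Models and methods: selective stopping with ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: selective stopping with ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selstopsig)
```

# The task and its bookkeeping

The package models a selective stop-signal session of 700 trials, split
equally into a *reactive* condition (non-informative cue) and a *proactive*
condition (informative arrow cue). Sixty percent of trials are go trials
(bimanual response to two white circles), forty percent are stop trials (a
red circle on one side instructs stopping that hand only, while the other
hand still responds). Stop trials are balanced over left and right within
each condition (70 each), giving per condition 210 go + 140 stop trials.
Timings default to a 200 ms cue, a 1300 ms fixation gap, a 100 ms go
stimulus and a 200 ms stop circle; all are configurable in
`design_params()`.

The stop-signal delay (SSD) — the interval between go-stimulus and
stop-signal onset — is drawn uniformly from a 50 ms grid spanning 50–500 ms.
We deliberately implement random (untracked) SSDs rather than an adaptive
staircase: it matches a design in which delays "vary randomly", and it keeps
the probability of responding given a signal estimable within a session.
The consequences of this choice for SSRT estimation are analysed below,
because they are substantial.

Trial order is a seeded pseudorandom permutation constrained to at most
three consecutive stop trials (configurable), the standard guard against
strategic slowing; conditions are interleaved in a single sequence since
nothing in the design requires blocking. `validate_schedule()` re-checks
every invariant and reports violations by trial index without raising.

# The horse-race model

Behaviour is generated by an independent race per hand. Go finish times are
ex-Gaussian, `mu + sigma`-Normal plus an Exponential tail with mean `tau`
(defaults 450/50/120 ms, a typical choice-RT shape); the stop process
latency is Gaussian truncated at zero (default mean 350 ms reactive /
340 ms proactive, SD 30 ms). On proactive trials every go finish is shifted
by `proactive_slowing_ms` (default 5 ms), modelling preparatory slowing; the
shift is additive and independent of the stop-latency group effects so the
two can be manipulated separately.

On a stop trial with delay `SSD`, the cued hand is inhibited iff

    SSD + stop latency < that hand's go finish time

and no trigger failure occurred (`trigger_failure_p`, default 0). The
non-cued hand always responds — the defining feature of *selective*
stopping. A failed selective stop produces a full bimanual response, or,
with probability `choice_error_p` (default 0.06), a wrong-hand pattern in
which only the to-be-stopped hand responds; these are the task's choice
errors. Go omissions occur with probability `go_omission_p` (default 0.05,
matching omission counts of roughly 20 in 420 go trials).

These defaults put mean go RT near 575 ms and session-level stop-success
around 40–60% across the SSD range, which is the regime the analysis
pipeline is meant to exercise; group-level presets in
`default_group_effects()` additionally mirror the *directions* of the
published group contrasts (faster go RTs, longer proactive stop latency and
more proactive choice errors, smaller cue-locked P3, smaller proactive N2
with larger proactive stop-P3 in the gaming group). The magnitudes are
plausible round numbers, not fits: no raw data are available to calibrate
against.

# Scoring behaviour and the integration-method SSRT

Trials are classified exhaustively into `go_correct`, `go_omission`,
`stop_success` (cued hand withheld), `stop_failed` (both hands responded)
and `stop_choice_error` (only the to-be-stopped hand responded). Both
failed stops and choice errors count as "responding" when estimating
p(respond | signal), since both are unsuccessful stops; a switch
(`choice_errors_respond`) exposes the alternative.

The stop-signal reaction time is estimated by the integration method: sort
the go RTs ascending, append one copy of the maximum RT per go omission
(the consensus guard against omission-induced underestimation), take the
RT at rank `ceiling(p_respond * n)` — the point where the integrated go-RT
distribution equals the response probability — and subtract the mean SSD of
the stratum's stop trials. The ceiling convention is exact when the rank is
integral and conservative otherwise. SSRT is computed per condition and
per stop direction, using that condition's go-RT distribution.

Two numerical choices deserve emphasis:

* **Which go RTs enter the quantile.** The estimate for stop-right trials
  uses the *right hand's* go RTs (and likewise for left), not the per-trial
  mean of the two hands. The race being estimated is the cued hand's own
  go process against the stop process; averaging two hands halves the RT
  variance and visibly distorts the quantile (about +17 ms at the 250 ms
  calibration point in our simulations). The per-trial mean remains
  available via `behavior_metrics(go_rt_hand = "mean")`, and is still used
  for the plain go-RT summary.

* **Attenuation under random SSDs.** With delays spread uniformly over
  50–500 ms, p(respond | signal) pools trials from the whole delay range,
  and the quantile-minus-mean-SSD construction inherits the curvature of
  the go-RT distribution function. Numerically integrating the estimator's
  asymptotic value shows a slope of roughly 0.45 of the estimate with
  respect to the true stop latency near the defaults: a 200 ms latency is
  over-estimated by ~28 ms, 300 ms under-estimated by ~27 ms, while at
  250 ms the estimate is essentially unbiased (the package's recovery
  checks run there: mean absolute error under 15 ms across 20 simulated
  sessions of 420 go / 280 stop trials). The same mechanism lets group
  differences in the go distribution leak into SSRT contrasts — a faster
  group's quantiles sit lower — so group comparisons of integration SSRT
  under untracked SSDs should be read with that caveat; the package's
  pipeline test isolates an injected stop-latency deficit by holding the
  go process equal across groups. None of this arises when SSDs are
  staircase-tracked to p ≈ 0.5, which is why tracking is the usual
  recommendation; this package implements the untracked design faithfully
  and documents its cost instead.

# Synthetic EEG

`simulate_eeg()` lays the schedule on a continuous timeline at 500 Hz over
channels Fz, F3, F4, Cz, C3, C4 and EOG and adds, per trial, Gaussian
bumps in time for the four components: a cue-locked P3 (frontal weights,
peak 400 ms, 4 µV), a go-locked P3 (central, 380 ms, 2.2 µV), and
stop-signal-locked N2 (frontal, 270 ms, −2 µV) and P3 (central, 380 ms,
3.2 µV). Peak latencies are constructed to lie inside the corresponding
measurement windows; temporal SD is 45 ms, narrow enough that the bump is
numerically zero in the baseline window. Scalp weighting is a per-channel
scalar — there is no forward head model — because a windowed peak
measurement only needs components with the right sign, latency and
topographic assignment.

On top of the components the generator adds 1/f-shaped background noise at
a configurable RMS (default 8 µV), Poisson blinks (default 4/min) as a
stereotyped 400 ms biphasic waveform, largest and sign-inverted on the EOG
channel and attenuated over frontal sites, and per-trial gross artifact
bursts (default probability 0.02, 150 µV) anchored inside the analysed
epoch. Blink onset samples and artifact trial indices are recorded as
ground truth so cleaning stages can be scored exactly. With noise, blinks
and artifacts disabled, each epoch equals its injected template to machine
precision — the identity on which the pipeline's round-trip checks rest.

What the generator does *not* emulate: realistic scalp topography and
volume conduction, trial-to-trial latency jitter and amplitude variability
of components, muscle and line noise, slow drifts beyond the 1/f model,
or any dependence of the EEG on behaviour (e.g. error-related activity).
Passing round-trip tests therefore show the *pipeline* is correct, not
that it would be robust to every pathology of real recordings.

# ERP conditioning and measurement

Processing mirrors standard ERP practice: zero-phase Butterworth filtering
in 0.1–45 Hz (a 2nd-order high-pass and 4th-order low-pass, each run
forward and backward with `signal::filtfilt`, after removing the channel
mean), epoching at −200…800 ms around cue, go or stop markers with a
−200…0 ms baseline (the window covers all measurement windows with a
conventional pre-stimulus baseline), rejection of any epoch exceeding
±100 µV on a scalp channel, and averaging per subject then per group.
Events too close to the record edge are flagged rather than raising.
Input is assumed linked-ear referenced; `rereference()` exists but is
never applied implicitly.

Blink correction decomposes the scalp channels with FastICA (symmetric
fixed-point iteration, log-cosh contrast, PCA whitening that drops
near-zero-variance dimensions) and zeroes every component whose time
course correlates with the EOG channel beyond |r| = 0.8 before
reconstructing. The EOG channel itself stays out of the decomposition so
it remains a clean regressor. The correlation rule is this package's
choice; the original analysis software's component selection is not
documented, and any rule that isolates the blink subspace serves the same
contract (≥50% RMS reduction in blink intervals on synthetic data, near
identity on blink-free data).

Components are measured on grand averages: P3-cue as the maximum between
300–550 ms, go- and stop-locked P3 as the maximum between 280–500 ms, and
the stop-locked N2 as the *second negative peak* in 200–350 ms. P3-cue and
N2 are taken at frontal electrodes (Fz/F3/F4), the go/stop P3 at central
electrodes (Cz/C3/C4); where the source material is ambiguous about the
cue-P3 site, we follow its results tables (frontal) rather than its prose,
since the tables record what was actually measured, and both sets remain
selectable. "Second negative peak" is operationalised as: among negative
local minima of the post-stimulus waveform ordered by latency, return the
one of overall rank two if it falls in the window; if the window contains
negative minima but none of rank two, return the most negative of them
flagged `"fallback"`; with none at all, return `NA` flagged `"missing"`
with a warning. The peak is a single sample (no around-peak smoothing), so
noiseless latencies are exact to one sample (2 ms at 500 Hz).

# Statistics

Group demographics and behavioural scores are compared with classical
pooled-variance Student t-tests (Welch available via a flag); with zero
pooled variance and equal means the conventional t = 0, p = 1 is returned.
ERP measures go into a mixed repeated-measures ANOVA — between-subjects
group, within-subjects trial condition × electrode for cue/go P3, stop
direction × electrode (per condition) for the stop-locked components —
computed as a univariate sums-of-squares decomposition with subject as the
blocking unit (`aov` with error strata). Partial eta squared is reported
per effect as SS_effect / (SS_effect + SS_error-of-its-stratum), which is
algebraically F·df1 / (F·df1 + df2). The design must be complete and
balanced; missing cells raise an explicit error naming the subjects, and
no imputation is ever applied. A Greenhouse–Geisser correction (epsilon
from the covariance of the effect's contrast scores) can be switched on
but is off by default, matching reports whose degrees of freedom are
uncorrected. Bonferroni adjustment multiplies by an explicit family size —
the number of planned follow-up comparisons within one effect — and caps
at 1. Participant screening applies the addiction-score cutoffs (eligible
for the gaming group at a mean-item score ≥ 2.5, for controls at ≤ 1.5,
neither in between).

Degrees of freedom are always derived from the package's own design
matrix. Published df pairs for comparable analyses are internally
inconsistent across effects, so no attempt is made to reproduce them.

# Problem sizes and calibration of the test-suite

The test-suite exercises full 700-trial sessions wherever the session
counts themselves are under test, and scaled designs (20–180 trials,
2–12 subjects per group) where only the mechanics matter. Stochastic
checks use fixed seeds and tolerances derived from the relevant sampling
error: SSRT recovery averages 20 sessions at the 250 ms calibration
point; the rejection-rate check uses one 700-epoch session against a
±0.05 band; null calibration runs 200 simulated measure-level studies at
8 subjects per group for the ANOVA and 1,000 replicates for the t-test,
asserting a rejection rate in [0.03, 0.08] at α = .05. The
sums-of-squares implementation is checked against an explicit
marginal-mean enumeration to 10⁻⁹ relative error, and the EDF writer
against an independent Python reader.

# Known limitations

* Integration-method SSRT under untracked SSDs is attenuated and
  go-distribution-dependent, as quantified above; recovered group
  differences are roughly halved.
* The EEG generator's simplifications (no forward model, no latency
  jitter, stationary noise) mean robustness claims stop at the synthetic
  boundary.
* The ANOVA handles complete balanced designs only, by construction.
* The EDF codec targets the package's own continuous recordings
  (equal-rate channels, 1-second records); it is not a general-purpose
  EDF+ implementation.
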