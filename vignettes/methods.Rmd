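---
title: "Methods: event detection in chronic EEG / diaphragm-EMG telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event detection in chronic EEG / diaphragm-EMG telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chronic telemetry in rodent epilepsy models yields two biopotential
channels recorded continuously for days to weeks: cortical EEG and raw
diaphragm EMG. From these two channels alone one can reconstruct a
remarkably complete picture of the animal's physiology: every breath (the
diaphragm is the inspiratory pump), every sigh and apnea, every
electrographic seizure, the postictal suppression that follows seizures,
sleep/wake state, the late transition to persistent epileptiform activity
(PEA), and finally the order in which breathing and the heart stop. That
ordering matters because respiratory failure preceding cardiac arrest is
the signature physiological cascade implicated in sudden unexpected death
in epilepsy (SUDEP).

`epivent` implements this analysis chain as composable detectors plus a
deterministic synthetic-recording generator. Because real telemetry has no
ground truth, the generator is the package's validation instrument: it
renders a fully programmed event schedule into realistic raw signals, and
every detector is scored against that schedule.

## Signal model and conventions

All times are 0-based seconds from recording start; all intervals are
half-open `[start, end)`. Amplitudes are arbitrary units throughout —
telemetry gain depends on electrode placement, which is why every
amplitude-bearing metric is normalized within animal (see below). Default
synthesis rates are 1000 Hz (EMG) and 500 Hz (EEG): high enough for the
60 Hz high-pass and for ECG spike morphology, and typical of implanted
transmitters.

## Breath extraction from diaphragm EMG

The conditioning chain is the field's standard one:

1. **High-pass at 60 Hz** (`emg_highpass()`), zero-phase Butterworth.
   Removes drift and motion artifact while keeping the broadband
   interference pattern of inspiratory bursts. Zero-phase filtering is used
   everywhere in the package because event *times* feed downstream logic
   (the apnea rule is a timing rule), and causal filters would bias them.
2. **Rectify and integrate** (`rectify_integrate()`): `|x|` averaged over a
   trailing window of 36–50 ms, default 40 ms (the midpoint of the
   accepted range). The window is wide relative to the ~8 ms cardiac
   spikes that contaminate diaphragm leads, so integration attenuates ECG
   roughly fivefold (window/width) while the ~80 ms inspiratory bursts pass
   through as smooth humps. A moving average was chosen over a leaky
   integrator; with a matched time constant the two differ only in kernel
   shape, and the moving average has an exactly invertible group delay.
3. **Burst segmentation** (`segment_breaths()`). The procedure is
   deliberately robust rather than clever:
   - a rolling 5 s median tracks the floor; because integration smears
     bursts to ~50% duty at 4 breaths/s, the median is computed twice,
     with samples more than 2 robust SDs above the first pass masked out
     of the second. The result follows the quiet inter-burst floor even
     under slow drift.
   - the floor-noise scale is estimated from the *negative* residual half
     (bursts only push the residual up), so burst amplitude cannot inflate
     the detection threshold.
   - bursts are samples above floor + 4 floor-SDs, with edges extended
     down to floor + 0.75 SD, merged below 30 ms gaps, dropped below
     20 ms duration, and subjected to a 50 ms refractory period.
   - the trailing integrator delays every edge by half its window; since
     `rectify_integrate()` annotates its window on the trace, the
     segmenter subtracts that known lag from the time stamps.

Per breath the table records onset, offset, peak (of the integrated
trace), inspiratory duration, area (integrated trace above floor), period
(onset-to-next-onset) and instantaneous frequency (1/period). Onset-to-
onset was chosen as the period convention because onsets are the sharpest,
most reliably detected landmark; the last breath has no defined period and
carries `NA`.

## Apneas, sighs and post-sigh apneas

The classification rules are threshold rules against trailing baselines:

- a **sigh** is a breath whose peak is at least **2×** the mean peak of the
  preceding 10 breaths in the same sleep/wake state (inclusive at the
  boundary: "at least twice");
- a **spontaneous apnea** is a pause whose cycle length is at least
  **2.5×** the mean period of the preceding 10 same-state breaths;
- an apnea whose pause begins within **8 s** after a sigh's offset
  (one-sided, inclusive) is relabelled a **post-sigh apnea** and excluded
  from spontaneous counts.

Where the rules needed interpretation, the package decides as follows, and
these choices are exposed as parameters:

- sighs are excluded from subsequent trailing baselines (one sigh must not
  mask the next), and sigh periods are excluded from the apnea baseline;
- with fewer than 10 eligible same-state predecessors, at least 5 are
  required and the mean is taken over what is available; otherwise the
  breath is not classified — trailing baselines at state entries would
  otherwise be unstable;
- the look-back never crosses more than 60 s, so a baseline cannot be
  stitched together across a long gap;
- an apnea's recorded time is the start of the pause (the offset of the
  breath preceding it) and its duration is the full long period.

Both detectors are verified, event for event, against independent
brute-force trailing-window scans on seeded breath trains up to 10,000
breaths.

## Seizures, PGES and PEA from cortical EEG

**Seizures** are abrupt increases in both amplitude and frequency: the
amplitude envelope (rectified 1–50 Hz signal, smoothed 1 s) must exceed
2× a robust rolling baseline, and the 95% spectral edge frequency within
the event must be at least 1.5× that of the preceding 60 s. Intervals
separated by less than 5 s are merged before the duration test; only
events strictly longer than 10 s are kept. The baseline is a 300 s
two-pass rolling median of the envelope (detected samples excluded from
the second pass): a median of that width cannot be captured by events up
to a couple of minutes long, and excluding detections keeps a dense
seizure cluster from inflating its own baseline. The amplitude ratio is
applied to the envelope (not power); the frequency criterion is the
configurable operationalization of "faster than baseline".

**PGES** (postictal generalized EEG suppression) is measured against a
100 s preictal power baseline: broadband (0.5–50 Hz) power is summarized
over the baseline's twenty 5 s windows as mean *m* and SD *s*, and
suppression ends at the first time the 5 s moving-window power reaches the
exit level *m − 3s*. The 5 s window is precisely what enforces "exceeded
for at least 5 s": an excursion shorter than the window cannot lift a full
window above the level, while one of at least the window length can. Two
numerical details matter:

- a 1 s guard after the seizure end keeps ictal power (and seizure-edge
  uncertainty) out of the first postictal window;
- a boxcar window crosses a power step with a lag of up to its own length,
  dependent on local power fluctuations, so the endpoint is refined to the
  first crossing of a mid-level threshold (suppressed level + 15% of the
  baseline contrast) by a 1 s forward power average near the coarse
  crossing. The level is far above what suppressed power can fluctuate to,
  yet low enough that recovered activity crosses it essentially without
  delay; this step-localization refinement is what brings the measured
  duration within a fraction of a second of the programmed suppression.
  When the baseline SD is large the exit level can sit close enough to the
  suppressed power that a 5 s window crosses it on a fluctuation alone;
  a coarse crossing with no corroborating mid-level recovery within one
  window length is therefore treated as a baseline fluctuation and the
  scan continues at the next exceedance run.

The measurement equals an independent per-sample endpoint-scan oracle on
seeded traces, and is monotone: deeper programmed suppression never
shortens the measured duration. On a baseline that is strongly
non-stationary (e.g. 100 s straddling a sleep-state transition) the
baseline SD grows until the exit level falls below the suppressed power
and the measured duration collapses to zero — a faithful property of the
3 SD criterion itself, not a defect; PGES is only well defined against a
reasonably stationary baseline.

**PEA onset** is the start of the first seizure beginning a run of at
least 3 consecutive interictal gaps all under 5 min, with no gap of 5 min
or more beginning within the following 30 min. The run-plus-look-ahead
construction is a deterministic proxy for "sustained transition with no
return to baseline".

**Disease staging** bins each day by seizure count (0, 1, 2–3, 4–5, 6–10,
11–20 per day; higher counts report in the top bin), then appends the
early-PEA window (2 h from PEA onset) and late-PEA window (2 h before
death). Days at or after PEA onset are not double-labelled and window
overlap resolves in favor of late PEA. Compressed simulated courses pass
their stage length as the "day".

## Sleep staging

States are scored in 10 s epochs from one-segment periodogram band powers:
delta 0.5–4 Hz, theta 4.5–8 Hz (10 s at 500 Hz gives 0.1 Hz resolution,
ample at the 0.5 Hz band edge). NREM requires delta/theta ≥ 1.5, epoch
RMS at least 0.9× the recording median (high-amplitude slow activity) and
tonic EMG no more than 3× its recording median (minimal EMG activity);
REM/inactive wake requires theta/delta ≥ 1.2. REM and inactive wake are
merged — separating them requires nuchal EMG, which two-lead transmitters
do not provide. The ratio and gate defaults are tuning choices, not
published constants; the band edges are the published ones. Priority
ordering is: epochs at/after PEA onset are OTH (sleep state is undefined
during PEA), then seizure epochs, then PGES, then movement (from the
externally supplied mask), then the spectral rule; `state_at()` resolves a
time to its epoch with half-open boundaries.

## Terminal analysis

`analyze_terminal()` requires a recording that ends with death (no breaths
in the final 60 s). The last breath is the final burst onset; the last
heartbeat is the final contaminating ECG R-peak recovered from the raw
EMG; `apnea_before_asystole` is true exactly when the former precedes the
latter, and indeterminate (not false) when no cardiac train is detectable.
EEG collapse is the first time 10 s-window broadband power falls below 10%
of the pre-terminal baseline and stays there. The terminal breathing
pattern over the final 10 min is classified as a tonic burst (final burst
longer than 5× the median inspiratory duration), irregular with apneas
(≥2 apneas), declining rate (frequency trend steeper than
−0.001 breaths/s per s), or mixed; when several apply, the most specific
(tonic > irregular > declining) wins. The 10% / 60 s collapse rule and the
pattern thresholds are package choices — the phenomena are described
qualitatively in the literature without printed criteria.

### ECG R-peak recovery from raw EMG

The cardiac field appears in diaphragm leads as narrow biphasic spikes.
After a 70 Hz zero-phase high-pass, candidate peaks come from a robust
amplitude threshold whose floor scale is the 20% quantile of 50 ms window
RMS values (windows between bursts and between beats see only the noise
floor). The beat period is then estimated as an approximate greatest
common divisor of quiet-region candidate spacings — bursts swallow
intermediate beats, so spacings cluster at integer multiples of the true
period, and the comb lag with the most chance-corrected multiple-hits wins.
Finally the train is tracked beat by beat on a near-rigid grid that
re-anchors only on quiet-region peaks; in-burst maxima confirm the count
but cannot drag the phase. Trailing sub-floor accepts are trimmed, and a
candidate train is rejected outright unless it fills most predicted beats,
beats on between bursts, and its quiet peaks stand well above the floor —
so an EMG with no cardiac contamination returns an empty list rather than
a hallucinated rhythm.

## The synthetic generator: what it emulates, and what it does not

`generate_recording()` renders a programmed schedule into raw signals:

- **EMG**: Gaussian noise floor (SD 0.05) + raised-cosine-enveloped white
  noise bursts (80 ms, amplitude 1) at quasi-periodic onsets
  (4 breaths/s, 2% inter-breath jitter — resting mouse eupnea) + an exact
  periodic biphasic ECG spike train (10 beats/s, 8 ms wide, amplitude
  0.3× burst amplitude). Sighs multiply a scheduled breath's amplitude by
  2.5; apneas stretch one scheduled inter-breath gap by the programmed
  ratio; a slowing profile scales frequency, amplitude and burst duration
  piecewise-linearly for late-disease deep slow breathing.
- **EEG**: broadband floor (SD 0.3) + band-limited noise per sleep block —
  0.5–4 Hz at RMS 3 in NREM, 4.5–8 Hz at RMS 1.8 in REM/inactive wake —
  alternating 240 s/120 s. Seizures replace the background with a tapered
  8 Hz sinusoid plus second harmonic scaled to the programmed multiple of
  the whole-recording background RMS; programmed suppression multiplies
  the background by 0.2 with a sharp 0.5 s cosine recovery (a clean exit,
  so the programmed duration is well defined to sub-second precision).
  After a terminal apnea, EEG power decays to 5% over 20 s.
- **Ground truth** carries every scheduled breath, sigh, apnea, seizure,
  suppression interval, ECG beat, per-epoch state, PEA onset and terminal
  time, with the same priority conventions the scorer uses.

`generate_disease_course()` composes stages with escalating daily seizure
rates (one Poisson draw per compressed "day", monotonicity enforced along
escalating rates), apnea incidence growing with seizure burden, progressive
slowing/deepening over the second half of the course, a PEA phase with
gaps of 2–4 min beginning a clear 350 s after the last stage, and terminal
apnea followed by asystole.

Scheduled apnea ratios default to 2.8–3.6, comfortably away from the 2.5
decision boundary: with 2% breathing jitter an exactly-boundary event is
ill-defined, so boundary behavior is tested on constructed noiseless
trains instead, and recovery is tested on unambiguous events.

The generator reproduces the statistical structure the detectors rely on —
band-limited state contrast, burst/ECG morphology and timing, event
amplitudes relative to baseline — but it is *not* biophysically realistic
EEG: no 1/f spectrum, no spindles or artifacts, no neural mass dynamics,
no video. Passing recovery tests therefore demonstrates that the detectors
implement their rules correctly at realistic signal-to-noise, not that
they are robust to every artifact of real telemetry; on real data the
exposed thresholds (MAD multipliers, band-ratio gates, SNR-dependent
floors) are the knobs that absorb the difference.

## Reproducibility and problem sizes

Every stochastic quantity derives from a single integer seed; identical
config plus seed gives bit-identical signals, and the pipeline is a pure
function of its configuration. The test suite validates detectors on
constructed noiseless inputs (boundary exactness), on 100 seeded breath
trains up to 10<sup>4</sup> breaths and 50 seeded EEG traces up to 600 s
(oracle equivalence), on ten 1 h synthetic recordings (event recovery),
and on ten terminal scenarios with apnea–asystole lags of 5–120 s. The
acceptance script re-runs the same analyses at slightly reduced scale
(six half-hour recordings, five terminal scenarios, one four-stage
compressed disease course) and reports the measured rates; these sizes
were chosen as the smallest at which the recovery statistics are stable.

## Known limitations

- Diaphragm EMG cannot assess expiration, airway patency or airflow;
  "apnea" here is strictly a prolonged inspiratory cycle.
- PGES duration is undefined against strongly non-stationary preictal
  baselines (the 3 SD criterion collapses), and the detector reports 0 in
  that regime.
- Offsets of bursts are intrinsically less sharp than onsets (the
  integrated trace decays over the window plus envelope tail), so
  inspiratory durations carry a small constant positive bias; amplitude
  and timing metrics are unaffected.
- The seizure detector is amplitude-first; electrographic events with no
  amplitude rise (pure rhythm changes) are out of reach by design.
- The movement mask is an input; no video analysis is performed.
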