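---
title: "Context-aware alert triage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware alert triage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Video-monitored long-term-care wards generate far more alerts than nurses
can act on. Most are non-actionable: the resident is fully dependent and
already attended, nobody could reach them in time anyway, or the motion
that tripped the detector is harmless. The resulting alarm fatigue is a
patient-safety hazard in its own right. `wardtriage` implements a staged
triage pipeline that decides, for every detected abnormal-behaviour event,
whether to alert at all, how long the alert may be deferred, how important
it is, and which nurse should receive it — and provides a seeded ward
simulator and an evaluation harness to study the pipeline under controlled
conditions.

## From pixels to context

All motion quantities derive from 2D pose keypoints in pixel coordinates.
With frame rate $f$ (frames/s) and calibration scale $s$ (m/px), the speed
of keypoint $i$ is $v_i(t) = s \cdot f \cdot \lVert P_i(t+1) - P_i(t)
\rVert$; the body speed aggregates $v_i$ over visible keypoints
(arithmetic mean by default, median available as a jitter-robust option —
the per-keypoint definition does not dictate a reduction, so we chose the
simplest unbiased one). Keypoints invisible at either end of a frame pair
are excluded; a pair with no visible keypoint yields an explicit undefined
speed, never a silent zero. Inter-person distances are Euclidean distances
between bounding-box centroids, always multiplied by $s$ before leaving
the motion module, so every threshold downstream is in meters. The scale
$s$ is a required per-room calibration input; the package never estimates
it. Planar centroid distance is a geometric approximation for wide-angle
ceiling cameras; we note it and do not correct it.

## Abnormal-behaviour detection

Abnormality is scored by forecast residuals on the vertical hip-joint
trajectory: a forecaster predicts the next position from the recent
window, and the score is the absolute residual $A(t) = |y(t) -
\hat y(t)|$, flagged when $A(t) > \tau_A$ (strictly). The forecaster is a
*contract* — any function mapping a history to predictions can be plugged
in — because the triage logic consumes residuals only, not the model
brand. The packaged default is rolling least-squares linear extrapolation
(window 10 frames): deterministic, dependency-free, and exact on
trajectories of degree $\le 1$, which gives the detector a clean
zero-false-positive baseline to test against.

Numerical choices:

* $\tau_A$ defaults to $k \cdot \mathrm{MAD}$ of the resident's own
  residual scores ($k = 3$), adapting to per-resident noise, with an
  absolute floor of 0.5 px. The floor guards the degenerate noiseless
  case, where the MAD collapses to zero and floating-point dust would
  otherwise be flagged. An absolute override is available.
* Flagged frames closer than `merge_gap_s` (6 s) are clustered, and a
  cluster becomes an event only if it contains at least `persist_s`
  (0.6 s) of flagged frames. This persistence (debounce) filter is
  standard alarm-engineering practice; it merges the rise and sit-back
  phases of one stand-up into one event and discards isolated jitter
  spikes.
* An event is labelled a stand-up attempt when the hip/shoulder midline
  rises (image *y* falls) at a peak rate of at least `standup_frac` (0.2)
  body-box heights per second over any one-second stretch around the
  cluster onset; the measurement window starts one second before the
  first flag so the onset is not truncated, and the box height is taken
  at cluster start, before the excursion inflates it.

## The five-part alarm context

Each event becomes an alarm tuple with temporal, spatial, urgency,
clinical and resource components:

* **Urgency** $u = \gamma_1 \sigma(v) + \gamma_2 \sigma(a) + \gamma_3
  \mathbf{1}[\text{risky activity}] + \gamma_4 \sigma_f(\text{flags})$
  with $\gamma = (0.2, 0.2, 0.25, 0.35)$: recurrent anomalies weigh most,
  then activity category, with velocity and acceleration equal. The
  squashing $\sigma(x) = x / (x + x_{\text{baseline}})$ is bounded and
  parameter-free, anchored at per-resident baselines (0.5 at the
  baseline); the flag count saturates at `flag_cap` (3). Acceleration is
  the first difference of body speed across consecutive windows — no
  standard definition exists for it at event level, so we state ours.
* **Clinical priority** maps the care level (CL 1–5) and five
  activity-assistance scores (AL 1–5) to `low` (CL 4–5, aggregated
  AL = 5: fully dependent, stationed attendant, alert non-actionable),
  `mid` (CL 1, AL 1: fully independent), `high` (everything between). ALs
  aggregate by maximum — worst-case dependency, the safety-first choice —
  with mean as an option.
* **Resource** is the on-duty busy fraction $r = \sum \text{task}(n) /
  |\text{nurses}|$.
* **Spatial** is the per-nurse distance map in meters. A nurse roster row
  carries both a task flag (`busy`, which feeds $r$) and an `available`
  flag (assignability): a stationed attendant is busy by duty yet can
  still respond to an alarm within reach, which is why the two are
  distinct.

## The three gates

1. **Suppression** discards an alarm when the nearest *available* nurse is
   beyond the reachable threshold $\theta_x = (\text{stand-up time} -
   \Delta t) \cdot v_{\text{nurse}}$ (defaults 3 s, 1 s, 1.2 m/s:
   $\theta_x = 2.4$ m), when urgency is below $\theta_u = 0.2$, or when
   the clinical class is `low` — in that clause order. The per-nurse
   distance map is reduced by the minimum over available nurses: an alarm
   is "too far" only if *nobody* can reach it. Discards go to a shadow
   log for audit.
2. **Delay** assigns $D = \alpha_1 (1 - u) + \alpha_2 r + \alpha_3
   \text{care}(c)$ with $\alpha = (0.5, 0.25, 0.25)$ and care-delay
   `high` → 0, `mid` → 1 (independent residents tolerate deferral). $D$
   is unitless in $[0, 1]$ and is scaled to seconds by `delay_scale`
   (10 s — the combination never states units, so the scale is explicit
   configuration). An alarm whose delay exceeds the acknowledgment
   horizon `t_ack` (30 s) strictly is discarded; one parameter serves
   both the delay gate and the acknowledgment timer, as the decision loop
   uses it in both roles.
3. **Validation** maps the alarm context and roster to a scalar priority
   in $[0, 1]$ and a recommended nurse through a pluggable backend. The
   default is a deterministic surrogate: $w_1 u + w_2\,\text{clin}(c) +
   w_3\,\text{prox} + w_4 (1 - r)$ with $w = (0.4, 0.3, 0.2, 0.1)$,
   $\text{prox} = \max(0, 1 - d/\theta_x)$; the recommended nurse
   maximizes the same score with that nurse's own distance, ties broken
   by lower workload index then id. The surrogate is an explicit stand-in
   for an external language-model backend — pluggable, logged, and not
   claimed to reproduce any particular model's judgments. The alarm is
   dispatched when priority $\ge \tau$ with the dynamic threshold $\tau =
   \mathrm{clamp}(\tau_0 + \beta_1 r + \beta_2 d/\theta_x - \beta_3
   \mathbf{1}[c = \text{high}])$.

A deliberate design choice: the default $\beta = (0.1, 0, 0.2)$ sets the
*distance* weight of the threshold to zero. The surrogate priority already
decreases with distance through its proximity term; raising the threshold
with distance as well double-counts distance and systematically discards
mid-priority alarms that are far but still reachable — exactly the alarms
the reachability gate was designed to keep. With $\beta_2 = 0$ the
validation gate cannot lose genuinely actionable alarms on clean data,
and the full pipeline is never worse than the rule-only pipeline there.
All three $\beta$ remain configurable.

**Dispatch and escalation.** The backend's ranking covers available
nurses within $\theta_x$ — alerting a nurse who cannot arrive in time is
non-actionable by construction. The first-ranked nurse is notified; on
acknowledgment failure the alert escalates down the ranking; if the
ranking is exhausted the alarm ends in an explicit `unanswered` terminal
state (the decision loop is silent on exhaustion, so we added one). Each
handled alert increments the assigned nurse's workload index before the
next alarm is processed; simultaneous alarms are handled in descending
urgency, ties by resident id. The engine does not temporally lock a nurse
for a service duration — no service-time model is specified anywhere, and
a history-dependent lock would make the programmatic ground-truth labels
ill-defined.

## The ward simulator

`simulate_ward()` emulates a lunchtime monitoring session: 28 residents
(6 high-, 8 medium-, 14 low-care) across 3 dining rooms of 8 m × 6 m,
4 nurses of whom 2 are stationed beside the fully dependent residents and
2 walk seeded waypoint paths at 1.2 m/s, sessions drawn uniformly from
30–60 min. Stand-up attempts arrive as Poisson events per resident-hour
at tier rates (low 10, medium 6, high 2 — mobile residents attempt to
stand far more often), about 200 facility events per hour, with at least
30 s between one resident's events. An event is a scripted torso
excursion: 0.35 m rise over 0.4 s, 2 s hold, 1 s sit-back, applied to the
upper 13 joints of a schematic 17-point stick figure. Keypoints get
Gaussian jitter (σ = 2 px) emulating pose-estimation noise; bounding
boxes derive from the noiseless skeleton (box noise is a detector
property, not a joint property). Frame rate defaults to 5 fps and the
scale to 0.01 m/px.

Acknowledgment behaviour is Bernoulli with `p_ack` = 0.9 and exponential
latency (mean 5 s, truncated at `t_ack`). The draws are *keyed* on
(seed, resident, event ordinal, nurse) through a small deterministic
mixing function rather than taken from the session RNG stream: any
consumer that knows the key sees the same outcome regardless of
evaluation order. This is what lets the ground-truth labeler and the
engine's escalation walk agree exactly, and what makes a full
simulate → triage → evaluate rerun byte-identical.

**Ground-truth labels** are a declared programmatic proxy for "which
nurse actually intervened": `none` for clinically low-priority residents
and for events no available nurse can reach within $\theta_x$; otherwise
the first nurse, by increasing distance among reachable available ones,
whose keyed acknowledgment draw succeeds. Making the label
acknowledgment-aware mirrors annotation semantics (the responder is the
label); a labeler blind to acknowledgments would count every escalation
as an error of the triage logic, which it is not.

What the simulator does **not** emulate: visual appearance, fisheye
geometry, occlusion and missed detections, inter-person interaction,
postural variety beyond the stand-up excursion, nurse task schedules.
Passing tests therefore demonstrate the correctness and calibration of
the triage logic under its stated assumptions, not performance on real
ward video.

## Evaluation

Decisions are matched to truth events per resident within a ±3 s window
(greedy nearest); a dispatched or escalated alarm predicts its final
handling nurse, anything else predicts the `none` ("no alert sent")
class; unmatched truth events are missed detections, unmatched decisions
are spurious ones. Metrics over the nurse classes plus `none`: per-class
precision/recall/F1 (0 and flagged when undefined, so macro averages are
conservative), accuracy, macro F1, and FPR/FNR computed one-vs-rest and
macro-averaged (the multi-class reduction must be stated — scalar error
rates are otherwise ambiguous). Four strategies run on the identical
detected stream: `baseline` (notify-all), `rsd` (suppression + delay),
`rsdv` (plus surrogate validation at fixed $\tau_0$), `proposed` (full
pipeline with dynamic threshold). For the confusion matrix the baseline's
predicted responder is the nearest on-duty nurse — notify-all has no
single predicted class, and the nearest nurse is the plausible first
responder — while its load accounting still counts one notification per
roster nurse per event. Per-nurse alarm load is reported relative to the
baseline, whose own load is 100% by construction.

## Problem sizes and reproducibility

The shipped tests exercise short sessions (2–8 min) for unit and
engine-level properties, ten 5-min sessions for disposition conservation,
and ten noise-free 60-min sessions (roughly 200 events each) for
assignment recovery — sizes chosen so the full suite completes in a few
minutes while every property is tested at meaningful event counts. The
`scripts/acceptance.R` entry point recomputes the headline quantities
from one full simulated session per run; all randomness flows from the
single `--seed` argument.

## Known limitations

* The surrogate validation backend is a transparent linear scorer; with
  clean synthetic data it rarely discards anything beyond what
  suppression already removes, so the validation stage shows its value
  only when a richer backend (or noisier data) is plugged in.
* Planar pixel geometry throughout; no camera model.
* Nurse availability is static apart from workload counters; no task
  schedule or service times.
* The stand-up classifier is a single-feature rule (vertical torso rate);
  `unstable_posture` is accepted as a risky label but never produced by
  the default detector.
* Event-level (not frame-level) evaluation is implemented; the
  alternative is noted as out of scope.
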