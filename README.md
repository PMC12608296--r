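# wardtriage

Context-aware triage of nurse alerts for video-monitored long-term-care
wards.

Conventional monitoring systems notify every nurse about every detected
event. In an elderly-care ward most of those alerts are non-actionable —
the resident is fully dependent and already attended, nobody could reach
them before they are standing anyway, or the motion was harmless — and the
resulting alarm fatigue erodes the response to the alerts that matter.
`wardtriage` is for researchers and engineers studying alert routing in
such settings: it implements a staged decision pipeline over pose-keypoint
streams, a seeded ward simulator with ground-truth labels, and an
evaluation harness comparing alerting strategies.

## The method

Every detected abnormal-behaviour event (pre-fall signatures such as
sudden stand-up attempts, flagged when the forecast residual of the hip
trajectory exceeds an adaptive threshold `τ_A = k·MAD`) becomes an alarm
tuple `a_i = (t_i, x_i, u_i, c_i, r_i)`: timestamp, per-nurse distance
map (meters), urgency, clinical priority class, and ward workload. The
tuple then passes three gates:

1. **Suppression** — discard if `x_i > θ_x` (nobody can reach within the
   stand-up time minus a 1 s response window), `u_i < θ_u`, or the
   resident's class is `low` (fully dependent, attendant stationed
   beside them), with
   `u = γ₁σ(v) + γ₂σ(a) + γ₃·1[risky activity] + γ₄σ(flags)`,
   `γ = (0.2, 0.2, 0.25, 0.35)`.
2. **Delay** — defer by `D = α₁(1−u) + α₂r + α₃·care(c)`,
   `α = (0.5, 0.25, 0.25)`; discard if the deferral would pass the
   acknowledgment horizon.
3. **Validation** — a pluggable backend maps the context to a priority in
   [0, 1] and a recommended nurse; dispatch iff priority ≥ a dynamic,
   context-dependent threshold. The packaged backend is a deterministic
   surrogate scorer; an external LLM can be plugged in behind the same
   contract.

Dispatched alerts go to the top-ranked reachable nurse and escalate down
the ranking on missed acknowledgments. Alarms surviving all gates form
the effective alert set `A*`; everything discarded is shadow-logged with
its reason.

## Worked example

```r
library(wardtriage)

session <- simulate_ward(scenario_config(session_minutes = c(10, 10)), seed = 42)
session
#> <ward_session> seed 42: 10.0 min, 28 residents, 4 nurses, 3 rooms, 33 truth events

run <- run_triage(session, triage_config(), strategy = "proposed")
run
#> <triage_run> strategy 'proposed': 33 alarms
#>   dispatched            9
#>   suppressed            23
#>   unanswered            1
```

Of 33 detected events, 23 were suppressed (unreachable, non-urgent, or
fully-attended residents), 9 were dispatched to a nurse, and for 1 no
reachable nurse acknowledged. Comparing the four alerting strategies on
the same stream against the simulator's ground-truth labels:

```r
cmp <- compare_strategies(session)
tidy(cmp)
#> # A tibble: 4 × 6
#>   strategy accuracy macro_f1    fpr   fnr n_events
#>   <chr>       <dbl>    <dbl>  <dbl> <dbl>    <int>
#> 1 baseline    0.265    0.189 0.180  0.24        34
#> 2 rsd         0.853    0.473 0.0738 0.137       34
#> 3 rsdv        0.853    0.473 0.0738 0.137       34
#> 4 proposed    0.853    0.473 0.0738 0.137       34

cmp$loads[cmp$loads$strategy == "proposed", 1:5]
#> # A tibble: 5 × 5
#>   nurse_id notifications baseline_notifications   load reduction
#>   <chr>            <dbl>                  <dbl>  <dbl>     <dbl>
#> 1 nurse1               0                     33 0          1
#> 2 nurse2               0                     33 0          1
#> 3 nurse3               4                     33 0.121      0.879
#> 4 nurse4               6                     33 0.182      0.818
#> 5 overall             10                    132 0.0758     0.924
```

The notify-all baseline assigns the nearest nurse to every event and
misclassifies most no-alert situations (accuracy 0.27); the rule-based
and full pipelines agree with the ground truth on 85% of events while
sending only ~8% of the baseline's notifications. Macro F1 averages over
all four nurse classes plus the "no alert" class and is conservative: a
nurse class with no events in a short session contributes 0.
`autoplot(cmp)` and `plot_alarm_load(cmp)` draw the corresponding
figures, and `shadow_log(run)` lists every suppressed alarm with its
reason.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/wardtriage.R simulate --seed 7 --out session/
Rscript inst/cli/wardtriage.R triage --stream session/stream.jsonl \
  --residents session/residents.csv --nurses session/nurses.csv \
  --seed 7 --out decisions.jsonl
```

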