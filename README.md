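# mstkit

Trial scheduling, scoring, and reliability simulation for the **Mnemonic
Similarity Task (MST)** — the recognition-memory paradigm that probes
hippocampal pattern separation with true repetitions, highly similar lures,
and novel foils.  The package is for task designers and memory researchers
who need to build MST variants, score response logs, and reason about how
design choices (format, prompt, trial counts, lags, repeat testing) affect
the psychometric quality of the task's scores — without collecting pilot
data for every candidate design.

## What it computes

Under the three-choice *old/similar/new* (OSN) prompt the primary outcome
is the lure discrimination index

LDI = p("similar" | lure) − p("similar" | foil),

with corrected recognition REC = p("old" | repeat) − p("old" | foil) as the
engagement screen (REC ≥ 0.5 for a valid session).  Under the two-choice
*old/new* (ON) prompt the analogues are d′(TL) = z(hit) − z(FA~lure~) and
d′(TF) = z(hit) − z(FA~foil~) (valid when d′(TF) ≥ 1.5).

Around these measures the package provides:

* **stimulus bank** — synthetic set/pair/lure-bin metadata (bin 1 = most
  similar lure), difficulty-matched half-set construction, subset sampling,
  CSV interface for real set metadata;
* **sequencer** — study-test and continuous schedules at full and reduced
  lengths (320 / 256 / 148 / 128 trials), lag-banded continuous placement
  (gaps 4–11 and 20–99), guided practice blocks, session counterbalancing,
  duration accounting, and an independent schedule checker;
* **scoring** — rate tables, LDI/REC/d′ with extreme-rate adjustment,
  per-bin lure curves, validity filtering, long-format export, CSV and
  jsPsych-style JSON logs;
* **simulator** — a generative signal-detection participant model
  (familiarity + lag-decaying recollection, lapses, trait-stable individual
  differences) plus a semi-analytic reliability oracle;
* **psychometrics** — robust regression with FDR outlier flagging
  (ROUT-style, Q = 1%), Fisher r-to-z comparisons, sample size for
  correlations, Cohen's d, common-vs-separate regression F-tests, and the
  baseline ↔ optimized score conversion line (0.33 + 0.65·x).

A thin CLI ships at `inst/cli/mst` (subcommands `generate`, `score`,
`simulate`, `reliability`, `power`, `replay`, `fixtures`).

## Worked example

Build the reduced continuous variant (the ~5-minute optimized task),
simulate a participant, and score the session:

```r
library(mstkit)
bank <- make_synthetic_bank(seed = 1)          # 6 sets x 192 pairs
set1 <- bank[bank$set_id == 1, ]
spec <- mst_variant_spec("reduced-cont", prompt = "OSN",
                         practice = TRUE, seed = 7)
schedule <- build_continuous(spec, set1)
schedule
#> MST schedule: reduced-cont / OSN - 137 trials
#>                 first lure repeat
#>   continuous       64   44     20
#>   practice_test     5    2      2
validate_schedule(schedule)$valid              # independent checker
#> [1] TRUE
estimate_duration(schedule) / 60               # minutes
#>      min_duration_s expected_duration_s
#>            5.333333            5.333333

log <- simulate_session(schedule, participant_params(), seed = 21)
score_session(log)
#> MST score report (OSN)
#>   LDI 0.438 | REC 0.934 | d'(TL) 2.319 | d'(TF) 3.799
#>   valid: TRUE - REC at or above threshold
```

The 128 scored trials give a 5.3-minute minimum session; this simulated
participant discriminated 43.8% more lures than response bias predicts and
passes the REC ≥ 0.5 engagement screen.  A test-retest cohort and the
variant-reliability analysis:

```r
co <- cohort_params()                          # young-adult defaults
sim <- simulate_cohort(schedule, co, n_participants = 40,
                       n_sessions = 2, seed = 3)
scores <- t(sapply(sim$logs, function(l)
  c(s1 = score_session(l[[1]])$ldi, s2 = score_session(l[[2]])$ldi)))
robust_fit_with_outliers(scores)               # ROUT-style, Q = 1%
#> Robust fit: y = 0.047 + 0.875 x (RSDR 0.210)
#>   r = 0.742 on 39 points after removing 1 outlier(s) (r_all 0.687)
predicted_reliability(schedule, co, n_sim = 4000, seed = 5)
#> [1] 0.7157607
sample_size_for_r(0.48, alpha = 0.05, power = 0.8)
#> [1] 32
convert_scores(0.30)    # baseline LDI -> optimized-variant scale
#> [1] 0.525
```

The observed between-session correlation (0.742 after one flagged outlier)
sits close to the semi-analytic prediction (0.716), illustrating the
attenuation machinery the package uses to compare candidate designs.

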