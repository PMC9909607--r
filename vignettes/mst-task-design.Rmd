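---
title: "Designing, scoring, and simulating the Mnemonic Similarity Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, scoring, and simulating the Mnemonic Similarity Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstkit)
```

## The task and its measures

The Mnemonic Similarity Task (MST) is a recognition-memory paradigm built
around three trial types: **repeats** (an exact re-presentation of a studied
object image), **lures** (a similar but not identical exemplar of a studied
object), and **foils** (novel objects).  Because correctly calling a lure
"similar" requires discriminating it from a highly overlapping stored trace,
performance on lures taxes hippocampal pattern separation, and the lure-based
score declines with age and hippocampal compromise while raw recognition is
spared.

Under the three-choice *old / similar / new* (OSN) prompt the primary
outcome is the **lure discrimination index**

$$\mathrm{LDI} = p(\text{"similar"} \mid \text{lure}) -
               p(\text{"similar"} \mid \text{foil}),$$

a difference score that removes bias in the use of the "similar" response.
The secondary outcome is corrected recognition,
$\mathrm{REC} = p(\text{"old"} \mid \text{repeat}) - p(\text{"old"} \mid
\text{foil})$.  Under the two-choice *old / new* (ON) prompt a
signal-detection framework replaces these with
$d'(\mathrm{TL}) = z(p(\text{old}\mid\text{repeat})) -
z(p(\text{old}\mid\text{lure}))$ and the analogous $d'(\mathrm{TF})$
against foils.

Each target/lure image pair carries a **lure bin** in 1–5, a difficulty
stratum derived from normative false-alarm rates.  Throughout this package
**bin 1 is the most similar (hardest) lure** and bin 5 the least similar.
The stimulus bank is modelled as metadata only (`set_id`, `pair_id`,
`lure_bin`); no images are involved.  The canonical synthetic bank has six
independent sets of 192 pairs with uniform bin weights — real MST sets are
not uniform, but no normative distribution is published, so uniform is the
documented default and real set metadata can be loaded from CSV.

## Schedule generation

Two formats are supported.  **Study-test**: an incidental-encoding phase
(every later-tested repeat and lure target shown once, exemplar *a*)
followed by a shuffled test phase of repeats (exemplar *a*), lures
(exemplar *b*), and foils.  The full-length design uses 128 study items and
64/64/64 test trials (320 trials); the reduced design protects lure trials,
allocating 20 repeats / 44 lures / 20 foils (148 trials).  **Continuous**: a
single interleaved block in which first presentations double as the novel
foils.  The full-length design has 128 firsts, 64 repeats, and 64 lures
(256 trials); the reduced design has 64/20/44 (128 trials).

Continuous probes must appear at a controlled **lag** (trials since the
first presentation).  The full-length design assigns 32 probes per
condition to the short band [4, 11] and 32 to the long band [20, 99].  For
reduced variants no canonical band allocation is published; the default
splits each condition as evenly as possible across the same two bands
(repeats 10/10, lures 22/22) and is overridable.  Placement uses a
randomized greedy algorithm: narrow bands are placed while the board is
empty, each probe samples its allowed lags in random order and takes a
uniformly random feasible slot pair, and a dead end restarts the whole
placement.  Restarts are bounded (default 10,000); the dense full-length
design — where every slot is either a first or a probe — needs a median of
about fifteen restarts, so generation is effectively always feasible, and an
infeasible request errors naming the band that failed.

Guided **practice blocks** reproduce the published structure: four practice
study trials plus six practice test trials (three guided, three unguided)
for study-test, and nine practice trials (five guided, four unguided) for
continuous.  Practice stimuli come from a reserved pool that is never
reused in the scored block.  Within a practice test block the guided trials
come first, and guided trials force the correct answer.

`validate_schedule()` is an independent checker: it re-derives condition
counts, pair-usage uniqueness, study coverage, exemplar conventions, lag
values, and band tallies from the raw trial list alone and compares them
with the declared design.  The generators are tested only through it.

Timing defaults follow the deployed task: 2.0 s stimulus duration, ≥ 0.5 s
inter-stimulus interval, and a 2.5 s minimum total trial length.  The
minimum session duration is `n_scored × min_trial_s`; the expected duration
substitutes an assumed response latency (default 1.5 s, measured from trial
onset) for the per-trial minimum only when the latency exceeds it.  The
deployed task's effective per-trial minimum is not fully pinned down by the
published phase medians, so duration estimates are parameterized rather
than hard-coded.  Reference median phase durations for the three variants
are bundled (`mst_reference_durations()`) and reproduce the published
totals: 12.24 min (baseline), 6.1 min (reduced study-test), 5.26 min
(reduced continuous, 43% of baseline — a 57% reduction).

`plan_sessions()` counterbalances task order across participants (rotation
assignment, balanced to within one) and, for four-session repeat-testing
studies, assigns difficulty-matched half-sets either re-used on session
pairs (1a, 1a, 2a, 2a) or all distinct (1a, 1b, 2a, 2b).  Half-sets are
built by `split_matched_halves()`: within each bin, shuffle then deal
alternately, handing odd bins' extra pair to the smaller half — per-bin
counts balance to ±1 and half sizes to ±1 by construction.

## Scoring

Rates are computed per condition over the scored block, with continuous
firsts mapped to the foil condition.  Omitted responses are excluded from
denominators by default (the prompts are self-paced, so omissions are
rare); a `count_as_new` policy is provided because the published analyses
do not state their convention, and both are tested.  $d'$ uses the standard
extreme-rate adjustment — 0 becomes $1/(2N)$ and 1 becomes $1 - 1/(2N)$ —
applied only when needed.  For OSN logs the $d'$ measures use the "old"
rates directly, which is exactly the two-choice collapse ("similar" counted
as "new").

Validity screening follows the published engagement filters and is
inclusive: OSN sessions need REC ≥ 0.5, ON sessions need $d'(\mathrm{TF})$
≥ 1.5 ("minimum of 0.5" is read as 0.5 passes); both thresholds are
configurable.  Sessions with extreme over- or under-use of the "similar"
response are *flagged for review, never dropped*: the published rule is
qualitative, so it is operationalized as overall $p(\text{"similar"})$
outside [0.05, 0.90].  Per-bin lure curves are computed but monotonicity
over bins is never enforced — it is an empirical property of the data.

## The generative participant model

Each trial evokes a familiarity value $x \sim \mathcal{N}(\mu, 1)$ (an
equal-variance signal-detection model):

* firsts, foils, study items: $\mu = 0$;
* repeats: $\mu = d_\mathrm{eff}$;
* lures from bin $b$: $\mu = d_\mathrm{eff} \cdot s_b$, with
  $s = (0.9, 0.75, 0.6, 0.45, 0.3)$ for bins 1–5 by default (no normative
  values are published; the vector is tunable and must be non-increasing).

$d_\mathrm{eff} = d_\mathrm{rep}\,((1+\mathrm{lag})/(1+\mathrm{lag_{ref}}))^{-\lambda}$
decays with log-lag ($\lambda = 0.15$); the reference lag of 160 trials is
the typical retention interval of the full-length study-test task, so
$d_\mathrm{rep}$ is calibrated at baseline and short-lag continuous designs
run above it.  For study-test probes the lag is the trial-index distance
back to the study presentation; for continuous probes it is the scheduled
gap.  OSN responses follow the two criteria ($x > c_\mathrm{old}$ → "old",
$x > c_\mathrm{sim}$ → "similar", else "new"); ON uses $c_\mathrm{old}$
alone.

A pure familiarity model cannot reproduce a key phenomenon: at short lags
overall performance rises, yet stronger memory pushes the hardest lures
*past* the "old" criterion, so $p(\text{"similar"}\mid\text{lure})$ — and
with it the LDI — stays flat or falls.  The model therefore adds a
**recollection** component: on probe trials, with probability
$r = r_\mathrm{base}\,((1+\mathrm{lag})/(1+\mathrm{lag_{ref}}))^{-0.8}$
(capped at 0.95), the study episode is retrieved and the correct response
is produced (lure → "similar" under OSN, "new" under ON).  Recollection is
also the main stable individual-difference driver of the LDI: its base
probability varies across participants (population mean 0.05, SD 0.20,
truncated to [0, 0.95]), which gives the LDI a true-score variance that
criteria and $d_\mathrm{rep}$ alone cannot supply.  A lapse process
(probability 0.02) substitutes a uniform random response.

Cohorts draw $d_\mathrm{rep}$ (mean 2.75, SD 0.8) and
$r_\mathrm{base}$ per session from a trait-plus-state decomposition: with
stability $\rho$, session latents are
$\mu + \sigma(\sqrt{\rho}\,A_i + \sqrt{1-\rho}\,E_{is})$, so any two
sessions correlate at $\rho$ (`retest_stability`, default 0.85).  Criteria
($c_\mathrm{old}$: mean 2.4, SD 0.15; $c_\mathrm{sim}$: mean 1.4, SD 0.15,
kept below $c_\mathrm{old}$) are stable traits.  A practice boost (+0.1 on
$d_\mathrm{rep}$ from session 2 onward) models the published
first-session-only improvement under repeat testing.  These defaults were
calibrated once, by closed-form normal arithmetic plus a single simulation
pass, to the study conditions of the task-optimization experiments: they
yield a full-length baseline LDI near 0.28–0.30 with population SD ≈ 0.15,
REC ≈ 0.65, roughly a quarter of sessions failing the validity screen, a
clearly higher LDI in the reduced continuous variant, and an attainable
test-retest reliability above 0.73.  An older-adult cohort is emulated
illustratively by lowering mean $d_\mathrm{rep}$ (no population parameters
for older adults are published).

With a fixed seed the familiarity draws are identical across prompts, so an
OSN session's collapsed "old" decisions coincide exactly with the matching
ON session's — the basis of a cross-prompt consistency test.

`predicted_reliability()` is a semi-analytic Spearman–Brown-type oracle: it
draws cohort latents, computes each participant-session's *expected* LDI
and its binomial measurement variance from the closed-form per-trial
response probabilities, and returns
$\mathrm{cov}(E_1, E_2)/\sqrt{(\mathrm{var}(E_1)+\bar V_1)(\mathrm{var}(E_2)+\bar V_2)}$.
It never replays trial-level responses, so it is an independent check on
the simulator–scorer path, and it can apply the same REC validity screen as
the analysis pipeline so that predictions refer to the screened population.
`tune_stability()` inverts it for a target reliability.

## Psychometric layer

**Robust correlation.** Between-variant reliability is estimated by robust
linear regression with FDR-controlled outlier flagging in the ROUT style:
iteratively reweighted least squares with Lorentzian weights
$1/(1+(e/\mathrm{RSDR})^2)$, a robust scale equal to the 68.27th percentile
of absolute residuals times $n/(n-K)$, and a sequential test from the
largest standardized residual down at rates $Q\,(n-i+1)/n$, stopping at the
first non-outlier ($Q = 1\%$ by default).  The exact commercial
implementation is not fully documented, so this follows the published
outline and is verified by *calibration* — on clean bivariate data the
false-flag rate stays at or below $Q$ and a planted gross outlier is
flagged exactly — rather than by bit-matching.  The reported correlation is
ordinary Pearson on the unflagged points, and the outlier-removed $n$ (not
the enrolled $n$) feeds the Fisher comparison.

**Fisher r-to-z.**
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)
/\sqrt{1/(n_1-3) + 1/(n_2-3)}$; the default one-tailed p-value tests
"variant correlation below reference" ($p = \Phi(z)$), matching how
variant-vs-baseline reliabilities are compared in practice.

**Sample size.**
$n = \lceil ((z_{1-\alpha/2} + z_{\mathrm{power}})/\operatorname{atanh} r)^2
+ 3 \rceil$; resolving $r = 0.48$ at $\alpha = 0.05$ and power 0.8 gives
32.  An independent brute-force oracle (bivariate-normal simulation with
common random numbers across candidate $n$) agrees to ±2.

**Model comparison and conversion.**  The extra-sum-of-squares F-test
compares a common regression against separate per-group fits on
$(2,\,n_1+n_2-4)$ degrees of freedom.  The shipped cross-variant conversion
line (optimized ≈ 0.33 + 0.65 × baseline) lives in the configuration
(`mst_defaults()`), not in code, and inverts algebraically.

## Numerical choices and degenerate inputs

* Seeded operations save and restore the caller's RNG state; sub-seeds are
  derived arithmetically and stay below $2^{31}$.
* The robust scale is floored relative to the largest residual
  ($10^{-8}\max|e|$) so that a gross outlier off an otherwise exact line is
  still flagged while floating-point noise is not; an all-zero residual fit
  flags nothing.
* Latent draws truncate at harmless bounds ($d_\mathrm{rep} \ge 0.05$,
  recollection in [0, 0.95], $c_\mathrm{sim} \le c_\mathrm{old} - 0.2$).
* Degenerate designs are legal where meaningful (a single repeat probe, a
  lag band of [1, 1] forcing adjacency, an empty schedule with zero
  duration) and rejected where not (zero variance in the regressor, fewer
  than five points for the robust fit, a foil count in the continuous
  format).
* Matched-half splitting breaks odd bins toward the currently smaller half,
  so the ±1 guarantees hold for any bin profile.

## What the tests do and do not show

The test suite exercises the whole pipeline on synthetic cohorts at sizes
chosen to keep the default run fast while leaving comfortable Monte Carlo
margins: 60 random designs for the schedule checker, 300 sessions for the
lure-bin curve trend, 60 cohorts of 50 for attenuation, 30 shared-seed
cohorts per design for trial-count monotonicity, 8 cohorts of 200 for
parameter recovery (a single cohort's correlation has sampling SD ≈ 0.04,
too coarse to certify a ±0.05 band honestly), and 200 replications of the
two-session baseline pipeline at $n = 47$ for the end-to-end reliability
replay.  The trial-count monotonicity property is tested as the task
designers actually manipulated it — trading repeat for lure trials at fixed
task length — because growing the lure count alone also lengthens the study
phase and thereby the retention lags, which empirically cancels the
binomial gain.

Passing these tests shows that the machinery is internally consistent and
reproduces the *structure* of the published findings (design arithmetic,
duration accounting, direction and rough size of format effects,
attenuation behaviour).  It does not show that the generative model is a
quantitatively faithful account of human participants: response times,
unequal-variance familiarity, fatigue and strategy drift, and real
non-compliance patterns are all outside the model, and the human
correlations themselves are not reproducible without human subjects.

## Known limitations

* The simulator ships no fitting routine; it generates but does not
  estimate (fitting the model to real logs is future work).
* The ON prompt's reliability analyses correlate $d'(\mathrm{TL})$ with a
  baseline LDI; `predicted_reliability()` currently covers the LDI path
  only.
* Mixed-effects modelling of multi-session data is deliberately out of
  scope: the package exports the tidy long table such models consume.
* Real stimulus-set bin compositions are not published; users with real
  metadata should load it through the bank CSV interface rather than rely
  on the uniform synthetic default.
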