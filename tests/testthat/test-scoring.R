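test_that("LDI and REC reproduce hand-counted rates", {
  log <- log_from_counts(list(
    "repeat" = c(old = 18, similar = 0, new = 2),
    "lure" = c(old = 10, similar = 22, new = 12),
    "foil" = c(old = 1, similar = 2, new = 17)))
  tab <- tabulate_responses(log)
  expect_equal(ldi(tab), 22 / 44 - 2 / 20) # 0.40
  expect_equal(rec(tab), 18 / 20 - 1 / 20) # 0.85
  expect_equal(sum(tab$counts), 84L)
  expect_equal(unname(tab$n_scored), c(20L, 44L, 20L))
})

test_that("LDI extremes behave: bias cancellation and the maximum", {
  same <- log_from_counts(list(
    "repeat" = c(old = 10, similar = 5, new = 5),
    "lure" = c(old = 4, similar = 10, new = 6),
    "foil" = c(old = 4, similar = 10, new = 6)))
  expect_equal(ldi(same), 0)
  maxed <- log_from_counts(list(
    "repeat" = c(old = 20, similar = 0, new = 0),
    "lure" = c(old = 0, similar = 20, new = 0),
    "foil" = c(old = 0, similar = 0, new = 20)))
  expect_equal(ldi(maxed), 1)
  expect_equal(rec(maxed), 1)
})

test_that("d-prime matches the normal-quantile oracle and adjusts extremes", {
  expect_equal(dprime(0.8, 0.2), 2 * qnorm(0.8))
  expect_equal(dprime(0.6, 0.6), 0)
  expect_equal(dprime(1, 0.5, n_signal = 20), qnorm(1 - 1 / 40) - qnorm(0.5))
  expect_equal(dprime(0.9, 0, n_noise = 32), qnorm(0.9) - qnorm(1 / 64))
  expect_error(dprime(1, 0.5), "count")
  expect_error(dprime(1.2, 0.5), "\\[0, 1\\]")
})

test_that("OSN old-rates equal the two-choice collapse for the d-primes", {
  # "similar" responses count as "new" for d'(TL)/d'(TF): old rates are
  # unaffected by how the non-old mass is split
  a <- log_from_counts(list(
    "repeat" = c(old = 15, similar = 3, new = 2),
    "lure" = c(old = 8, similar = 20, new = 16),
    "foil" = c(old = 2, similar = 4, new = 14)))
  b <- log_from_counts(list(
    "repeat" = c(old = 15, new = 5),
    "lure" = c(old = 8, new = 36),
    "foil" = c(old = 2, new = 18)), prompt = "ON")
  expect_equal(dprime_tl(a), dprime_tl(b))
  expect_equal(dprime_tf(a), dprime_tf(b))
})

test_that("validity thresholds are inclusive and prompt-specific", {
  mk <- function(rec, dtf, prompt) {
    list(rec = rec, dprime_tf = dtf, prompt = prompt)
  }
  expect_false(validity_filter(mk(0.49, NA, "OSN"))$valid)
  expect_true(validity_filter(mk(0.50, NA, "OSN"))$valid)
  expect_true(validity_filter(mk(NA, 1.6, "ON"))$valid)
  expect_true(validity_filter(mk(NA, 1.5, "ON"))$valid)
  expect_false(validity_filter(mk(NA, 1.49, "ON"))$valid)
  # thresholds are configurable
  expect_true(validity_filter(mk(0.4, NA, "OSN"), rec_min = 0.3)$valid)
})

test_that("omission policies change denominators as documented", {
  log <- log_from_counts(list(
    "repeat" = c(old = 9, new = 0, none = 1),
    "lure" = c(similar = 2, new = 1, none = 1),
    "foil" = c(similar = 0, new = 2, none = 0)))
  tab_ex <- tabulate_responses(log, "exclude")
  expect_equal(tab_ex$rates["lure", "similar"], 2 / 3)
  expect_equal(tab_ex$rates["repeat", "old"], 1)
  expect_equal(unname(tab_ex$n_omitted[c("repeat", "lure")]), c(1L, 1L))
  tab_cn <- tabulate_responses(log, "count_as_new")
  expect_equal(tab_cn$rates["lure", "similar"], 2 / 4)
  expect_equal(tab_cn$rates["repeat", "old"], 9 / 10)
})

test_that("scores are invariant to trial order and pair relabeling", {
  sch <- build_study_test(mst_variant_spec("reduced-st", seed = 3), bank_set(1))
  log <- simulate_session(sch, participant_params(), seed = 17)
  r0 <- score_session(log)
  shuffled <- log[sample.int(nrow(log)), ]
  relabeled <- shuffled
  relabeled$pair_id <- relabeled$pair_id + 1000L
  r1 <- score_session(response_log(relabeled, prompt = "OSN"))
  expect_equal(r1$ldi, r0$ldi)
  expect_equal(r1$rec, r0$rec)
  expect_equal(r1$dprime_tl, r0$dprime_tl)
})

test_that("response vocabulary is validated per prompt with a row number", {
  df <- data.frame(trial_index = 1:3, phase = "test",
                   condition = c("repeat", "lure", "foil"),
                   set_id = 1L, pair_id = 1:3, exemplar = "a",
                   lure_bin = 1L, lag = NA_integer_,
                   response = c("old", "similar", "new"))
  expect_error(response_log(df, prompt = "ON"), "row 2")
  expect_silent(response_log(df, prompt = "OSN"))
})

test_that("LDI is undefined for two-choice logs and empty conditions error", {
  on_log <- log_from_counts(list(
    "repeat" = c(old = 5, new = 5),
    "lure" = c(old = 5, new = 5),
    "foil" = c(old = 1, new = 9)), prompt = "ON")
  expect_error(ldi(on_log), "OSN")
  no_lure <- log_from_counts(list(
    "repeat" = c(old = 5, new = 5),
    "foil" = c(similar = 1, new = 9)))
  expect_error(ldi(no_lure), "lure")
})

test_that("extreme over-use of 'similar' is flagged for review, not dropped", {
  allsim <- log_from_counts(list(
    "repeat" = c(similar = 18, old = 2),
    "lure" = c(similar = 20),
    "foil" = c(similar = 19, new = 1)))
  rp <- score_session(allsim)
  expect_true(rp$flag_similar_use)
  expect_gt(rp$p_similar_overall, 0.9)
  balanced <- log_from_counts(list(
    "repeat" = c(old = 16, similar = 2, new = 2),
    "lure" = c(old = 5, similar = 9, new = 6),
    "foil" = c(old = 1, similar = 2, new = 17)))
  expect_false(score_session(balanced)$flag_similar_use)
})

test_that("per-bin lure curves track bin similarity across simulated sessions", {
  sch <- build_study_test(mst_variant_spec("full-st", seed = 23), bank_set(3))
  draw <- draw_participants(cohort_params(), 300, 1L, seed = 71)
  curves <- vapply(seq_len(300), function(i) {
    log <- simulate_session(sch, mstkit:::participant_from_draw(draw, i, 1),
                            seed = 5000 + i)
    bin_curve(log)$old_rate
  }, numeric(5))
  means <- rowMeans(curves, na.rm = TRUE)
  # more similar lure (bin 1) -> more "old" false alarms, monotone over bins
  expect_true(all(diff(means) < 0))
  # per-session sign test, bin 1 vs. bin 5
  d <- curves[1, ] - curves[5, ]
  d <- d[!is.na(d) & d != 0]
  pv <- binom.test(sum(d > 0), length(d))$p.value
  expect_lt(pv, 1e-6)
})

test_that("long-format export flattens reports tidily", {
  log <- log_from_counts(list(
    "repeat" = c(old = 18, similar = 0, new = 2),
    "lure" = c(old = 10, similar = 22, new = 12),
    "foil" = c(old = 1, similar = 2, new = 17)))
  attr(log, "participant") <- "p1"
  attr(log, "variant") <- "reduced-st"
  out <- scores_long(list(score_session(log), score_session(log)),
                     sessions = 1:2)
  expect_equal(nrow(out), 8L)
  expect_setequal(unique(out$metric),
                  c("ldi", "rec", "dprime_tl", "dprime_tf"))
  expect_equal(out$value[out$metric == "ldi" & out$session == 1], 0.4)
})
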