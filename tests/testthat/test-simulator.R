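test_that("simulated rates match the closed-form normal probabilities", {
  # big session so binomial error is small; decay/recollection/lapse off
  bank <- canonical_bank()
  spec <- design_spec("study_test", "OSN", n_repeat = 300, n_lure = 300,
                      n_foil = 300, seed = 41)
  sch <- build_study_test(spec, bank)
  pp <- participant_params(d_rep = 3, bin_similarity = rep(0, 5),
                           c_old = 1.5, c_sim = 0, lapse_rate = 0,
                           lag_decay = 0, rec_base = 0)
  # the analytic layer reduces to the plain normal-CDF expressions
  probs <- trial_response_probs(sch, pp)
  expect_equal(mean(probs$p_old[probs$condition == "repeat"]), pnorm(1.5))
  expect_equal(mean(probs$p_similar[probs$condition == "lure"]),
               pnorm(1.5) - pnorm(0))
  expect_true(all(abs(probs$p_old + probs$p_similar + probs$p_new - 1) < 1e-12))

  log <- simulate_session(sch, pp, seed = 42)
  tab <- tabulate_responses(log)
  se3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(tab$rates["repeat", "old"] - pnorm(1.5)),
            se3(pnorm(1.5), 300))
  expect_lt(abs(tab$rates["lure", "similar"] - (pnorm(1.5) - 0.5)),
            se3(pnorm(1.5) - 0.5, 300))
  expect_lt(abs(tab$rates["foil", "similar"] - (pnorm(1.5) - 0.5)),
            se3(pnorm(1.5) - 0.5, 300))
})

test_that("a null participant shows no recognition signal", {
  bank <- canonical_bank()
  spec <- design_spec("study_test", "OSN", n_repeat = 300, n_lure = 300,
                      n_foil = 300, seed = 43)
  sch <- build_study_test(spec, bank)
  pp <- participant_params(d_rep = 0.0001, bin_similarity = rep(0, 5),
                           c_old = 1.5, c_sim = 0, lapse_rate = 0,
                           lag_decay = 0, rec_base = 0)
  r <- rec(tabulate_responses(simulate_session(sch, pp, seed = 44)))
  p <- 1 - pnorm(1.5)
  expect_lt(abs(r), 3 * sqrt(2 * p * (1 - p) / 300))
})

test_that("sessions are reproducible and prompts share familiarity draws", {
  set1 <- bank_set(1)
  schO <- build_study_test(mst_variant_spec("full-st", "OSN", seed = 3), set1)
  schN <- build_study_test(mst_variant_spec("full-st", "ON", seed = 3), set1)
  pp <- participant_params(lapse_rate = 0)
  a <- simulate_session(schO, pp, seed = 42)
  b <- simulate_session(schO, pp, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$response,
                         simulate_session(schO, pp, seed = 43)$response))
  # same seed, same criteria: the "old" decisions coincide across prompts,
  # so the OSN log's collapsed d'(TL) equals the ON log's d'(TL)
  on_log <- simulate_session(schN, pp, seed = 42)
  expect_identical(a$response == "old", on_log$response == "old")
  expect_equal(dprime_tl(a), dprime_tl(on_log))
  expect_equal(dprime_tf(a), dprime_tf(on_log))
})

test_that("latent draws respect the trait-state stability structure", {
  co <- cohort_params(retest_stability = 0.85, practice_boost = 0)
  draw <- draw_participants(co, 20000, 2L, seed = 55)
  expect_lt(abs(cor(draw$d_rep[, 1], draw$d_rep[, 2]) - 0.85), 0.02)
  expect_lt(abs(sd(draw$d_rep[, 1]) - co$sd_d_rep), 0.02)
  boosted <- draw_participants(cohort_params(practice_boost = 0.3), 20000, 2L,
                               seed = 56)
  expect_lt(abs(mean(boosted$d_rep[, 2]) - mean(boosted$d_rep[, 1]) - 0.3),
            0.02)
})

test_that("predicted reliability rises with stability and lure count", {
  sch <- build_study_test(mst_variant_spec("full-st", seed = 5), bank_set(1))
  co <- cohort_params()
  rhos <- c(0.3, 0.6, 0.9)
  preds <- vapply(rhos, function(r) {
    co$retest_stability <- r
    predicted_reliability(sch, co, n_sim = 4000, seed = 6)
  }, numeric(1))
  expect_true(all(diff(preds) > 0))
  expect_true(all(preds > 0 & preds < 1))
  # more lure trials at fixed task length -> higher predicted reliability
  lure_preds <- vapply(list(c(73, 11), c(40, 44), c(20, 64)), function(cc) {
    s <- build_study_test(design_spec("study_test", "OSN", n_repeat = cc[1],
                                      n_lure = cc[2], n_foil = 64, seed = 8),
                          bank_set(1))
    predicted_reliability(s, co, n_sim = 4000, seed = 6)
  }, numeric(1))
  expect_true(all(diff(lure_preds) > 0))
})

test_that("observed test-retest correlation is attenuated below stability", {
  sch <- build_continuous(mst_variant_spec("reduced-cont", seed = 9),
                          bank_set(1))
  co <- cohort_params()
  rs <- vapply(1:10, function(k) {
    sc <- cohort_ldi_pairs(sch, co, 50, seed = 6000 + k)
    cor(sc[, 1], sc[, 2])
  }, numeric(1))
  expect_lt(mean(rs), co$retest_stability)
})

test_that("short-lag continuous designs raise the LDI above baseline", {
  co <- cohort_params()
  base <- build_study_test(mst_variant_spec("full-st", seed = 10), bank_set(1))
  cont <- build_continuous(mst_variant_spec("reduced-cont", seed = 11),
                           bank_set(2))
  ldi_base <- cohort_ldi_pairs(base, co, 150, seed = 77)[, 1]
  ldi_cont <- cohort_ldi_pairs(cont, co, 150, seed = 77)[, 1]
  expect_gt(mean(ldi_cont), mean(ldi_base))
})

test_that("cohort simulation tags logs and reuses schedules per session", {
  sch <- build_study_test(mst_variant_spec("reduced-st", seed = 12),
                          bank_set(1))
  sim <- simulate_cohort(sch, cohort_params(), 3, 2, seed = 13)
  expect_length(sim$logs, 3L)
  expect_length(sim$logs[[1]], 2L)
  expect_equal(attr(sim$logs[[2]][[1]], "participant"), 2)
  expect_equal(dim(sim$draw$d_rep), c(3L, 2L))
  expect_true(all(sim$draw$c_sim < sim$draw$c_old))
})

test_that("participant parameters are validated", {
  expect_error(participant_params(bin_similarity = c(0.3, 0.45, 0.6, 0.75, 0.9)),
               "non-increasing")
  expect_error(participant_params(lapse_rate = 0.5), "lapse")
  expect_error(participant_params(c_old = 1, c_sim = 1.5), "c_sim")
  expect_error(cohort_params(retest_stability = 1.2), "retest_stability")
})
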