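test_that("canonical variants produce the expected trial structure", {
  set1 <- bank_set(1)
  sizes <- c("full-st" = 320L, "full-cont" = 256L,
             "reduced-st" = 148L, "reduced-cont" = 128L)
  for (v in names(sizes)) {
    sch <- build_schedule(mst_variant_spec(v, "OSN", seed = 13), set1)
    ck <- validate_schedule(sch)
    expect_true(ck$valid, info = paste(v, paste(ck$problems, collapse = "; ")))
    expect_equal(nrow(sch$trials), sizes[[v]])
  }
  # study/test split of the full-length task
  sch <- build_study_test(mst_variant_spec("full-st", seed = 1), set1)
  expect_equal(sum(sch$trials$phase == "study"), 128L)
  expect_equal(sum(sch$trials$phase == "test"), 192L)
})

test_that("a minimal one-of-each design yields 2 study + 3 test trials", {
  sch <- build_study_test(
    design_spec("study_test", "OSN", n_repeat = 1, n_lure = 1, n_foil = 1,
                seed = 4), bank_set(1))
  expect_equal(nrow(sch$trials), 5L)
  expect_equal(sum(sch$trials$phase == "study"), 2L)
  tt <- sch$trials[sch$trials$phase == "test", ]
  expect_setequal(tt$condition, c("repeat", "lure", "foil"))
  expect_true(validate_schedule(sch)$valid)
})

test_that("a lag band of [1,1] forces the repeat to follow its first", {
  spec <- design_spec("continuous", "OSN", n_first = 2, n_repeat = 1,
                      n_lure = 0,
                      lag_bands = data.frame(lo = 1, hi = 1,
                                             n_repeat = 1, n_lure = 0),
                      seed = 8)
  sch <- build_continuous(spec, bank_set(1))
  tr <- sch$trials
  rep_row <- tr[tr$condition == "repeat", ]
  expect_equal(rep_row$lag, 1L)
  prev <- tr[tr$trial_index == rep_row$trial_index - 1L, ]
  expect_equal(prev$pair_id, rep_row$pair_id)
  expect_true(validate_schedule(sch)$valid)
})

test_that("full continuous schedules meet the 32/32 lag-band allocations", {
  sch <- build_continuous(mst_variant_spec("full-cont", "OSN", seed = 21),
                          bank_set(2))
  tr <- sch$trials
  for (co in c("repeat", "lure")) {
    lags <- tr$lag[tr$condition == co]
    expect_equal(sum(lags >= 4 & lags <= 11), 32L)
    expect_equal(sum(lags >= 20 & lags <= 99), 32L)
  }
})

test_that("duration estimates follow the timing arithmetic", {
  sch <- build_study_test(
    design_spec("study_test", "OSN", n_repeat = 32, n_lure = 32, n_foil = 64,
                seed = 2), bank_set(1))
  # 64 study + 128 test = 192... use the 128-trial case via scored count
  expect_equal(sum(!startsWith(sch$trials$phase, "practice")), 192L)
  est <- estimate_duration(sch)
  expect_equal(unname(est["min_duration_s"]), 192 * 2.5)

  # 128 scored trials at the 2.5 s minimum
  sch128 <- build_continuous(mst_variant_spec("reduced-cont", seed = 3),
                             bank_set(1))
  expect_equal(unname(estimate_duration(sch128)["min_duration_s"]), 320)

  # zero trials
  empty <- sch
  empty$trials <- sch$trials[0, ]
  expect_equal(unname(estimate_duration(empty)["min_duration_s"]), 0)
  expect_equal(unname(estimate_duration(empty)["expected_duration_s"]), 0)

  # a response latency below the per-trial minimum leaves expected = minimum
  sch84 <- build_study_test(
    design_spec("study_test", "OSN", n_repeat = 10, n_lure = 22, n_foil = 20,
                timing = timing_spec(assumed_response_latency_s = 1.0),
                seed = 5), bank_set(1))
  # 32 study + 52 test = 84 scored trials
  expect_equal(unname(estimate_duration(sch84)["expected_duration_s"]),
               84 * 2.5)
  # a latency above it drives the expected duration
  est2 <- estimate_duration(sch84,
                            timing_spec(assumed_response_latency_s = 3.0))
  expect_equal(unname(est2["expected_duration_s"]), 84 * 3.0)
  expect_gte(est2[["expected_duration_s"]], est2[["min_duration_s"]])
})

test_that("practice blocks carry the specified counts and guided flags", {
  st <- build_study_test(mst_variant_spec("reduced-st", practice = TRUE,
                                          seed = 6), bank_set(1))
  pr <- st$trials[startsWith(st$trials$phase, "practice"), ]
  expect_equal(sum(pr$phase == "practice_study"), 4L)
  expect_equal(sum(pr$phase == "practice_test"), 6L)
  expect_equal(sum(pr$guided[pr$phase == "practice_test"]), 3L)
  expect_true(validate_schedule(st)$valid) # incl. reserved-pool disjointness

  ct <- build_continuous(mst_variant_spec("reduced-cont", practice = TRUE,
                                          seed = 7), bank_set(1))
  pc <- ct$trials[startsWith(ct$trials$phase, "practice"), ]
  expect_equal(nrow(pc), 9L)
  expect_equal(sum(pc$guided), 5L)
  expect_true(validate_schedule(ct)$valid)
  # practice stimuli never reused in the scored block
  sc <- ct$trials[!startsWith(ct$trials$phase, "practice"), ]
  expect_length(intersect(paste(pc$set_id, pc$pair_id),
                          paste(sc$set_id, sc$pair_id)), 0L)
})

test_that("session plans counterbalance order and stimulus reuse", {
  plan <- plan_sessions(4, c("baseline", "variant"), sets_available = 1:2,
                        mode = "counterbalanced_order", seed = 1)
  firsts <- plan$variant[plan$session == 1]
  expect_equal(sum(firsts == "baseline"), 2L)
  expect_equal(sum(firsts == "variant"), 2L)
  # each participant sees each variant once
  expect_true(all(tapply(plan$variant, plan$participant,
                         function(v) length(unique(v))) == 2))

  rep_plan <- plan_sessions(6, "half-st", sets_available = 1:5,
                            mode = "repeat", seed = 2)
  for (i in 1:6) {
    labs <- rep_plan$stim_label[rep_plan$participant == i]
    expect_identical(labs[1], labs[2])
    expect_identical(labs[3], labs[4])
    expect_false(labs[1] == labs[3])
  }
  nr_plan <- plan_sessions(6, "half-st", sets_available = 1:5,
                           mode = "no_repeat", seed = 3)
  for (i in 1:6) {
    labs <- nr_plan$stim_label[nr_plan$participant == i]
    expect_equal(length(unique(labs)), 4L)
  }
})

test_that("identical seeds reproduce identical schedules", {
  set1 <- bank_set(1)
  for (v in c("full-st", "full-cont")) {
    a <- build_schedule(mst_variant_spec(v, seed = 33), set1)
    b <- build_schedule(mst_variant_spec(v, seed = 33), set1)
    expect_identical(a$trials, b$trials)
  }
  a <- build_continuous(mst_variant_spec("full-cont", seed = 33), set1)
  b <- build_continuous(mst_variant_spec("full-cont", seed = 34), set1)
  expect_false(identical(a$trials, b$trials))
})

test_that("the schedule checker validates randomly drawn designs", {
  bank <- canonical_bank()
  set.seed(99)
  for (k in 1:60) {
    if (k %% 2 == 0) {
      spec <- design_spec("study_test", sample(c("OSN", "ON"), 1),
                          n_repeat = sample(1:40, 1),
                          n_lure = sample(1:40, 1),
                          n_foil = sample(1:40, 1),
                          practice = if (k %% 4 == 0) practice_spec("study_test"),
                          seed = 1000 + k)
    } else {
      n_rep <- sample(1:16, 1)
      n_lure <- sample(1:16, 1)
      n_first <- n_rep + n_lure + sample(10:40, 1)
      spec <- design_spec("continuous", "OSN", n_first = n_first,
                          n_repeat = n_rep, n_lure = n_lure,
                          practice = if (k %% 5 == 0) practice_spec("continuous"),
                          seed = 1000 + k)
    }
    sch <- build_schedule(spec, bank)
    ck <- validate_schedule(sch)
    expect_true(ck$valid, info = paste("spec", k, ":",
                                       paste(ck$problems, collapse = "; ")))
  }
})

test_that("the checker flags schedules that break their declared design", {
  sch <- build_study_test(mst_variant_spec("reduced-st", seed = 2), bank_set(1))
  broken <- sch
  broken$trials$condition[broken$trials$phase == "test"][1] <- "foil"
  expect_false(validate_schedule(broken)$valid)
  broken2 <- sch
  i <- which(broken2$trials$condition == "lure")[1]
  broken2$trials$exemplar[i] <- "a"
  expect_false(validate_schedule(broken2)$valid)
})

test_that("builders reject infeasible or ill-typed requests", {
  set1 <- bank_set(1)
  expect_error(build_study_test(mst_variant_spec("full-st", seed = 1),
                                set1[1:100, ]), "insufficient")
  expect_error(design_spec("continuous", "OSN", n_first = 10, n_repeat = 8,
                           n_lure = 8), "n_first")
  expect_error(design_spec("continuous", "OSN", n_first = 20, n_repeat = 4,
                           n_lure = 4, n_foil = 4), "foil")
  expect_error(design_spec("continuous", "OSN", n_first = 20, n_repeat = 4,
                           n_lure = 4,
                           lag_bands = data.frame(lo = 0, hi = 5,
                                                  n_repeat = 4, n_lure = 4)),
               "lo")
  expect_error(design_spec("study_test", "OSN", n_repeat = 4, n_lure = 4,
                           n_foil = 4,
                           practice = practice_spec("continuous")),
               "format")
  # an impossible lag band reports the constraint that failed
  expect_error(build_continuous(
    design_spec("continuous", "OSN", n_first = 2, n_repeat = 2, n_lure = 0,
                lag_bands = data.frame(lo = 50, hi = 99,
                                       n_repeat = 2, n_lure = 0),
                seed = 1),
    bank_set(1), max_attempts = 50), "\\[50,99\\]")
})
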