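# Generative signal-detection participant model.
#
# Each trial evokes a familiarity value x ~ Normal(mu, 1):
#   mu = 0                          first presentations / foils / study items
#   mu = d_eff                      true repetitions
#   mu = d_eff * bin_similarity[b]  lures from difficulty bin b (bin 1 most
#                                   similar, matching the bank's polarity)
# where d_eff = d_rep * ((1 + lag) / (1 + lag_ref))^(-lag_decay) decays with
# log-lag (lag = trials since the first presentation; lag_ref is the typical
# baseline study-test retention interval, so full-length study-test runs at
# roughly d_rep while short-lag continuous designs run above it).
#
# Responses under the OSN prompt: "old" if x > c_old, "similar" if
# c_sim < x <= c_old, else "new"; under ON: "old" iff x > c_old.  On probe
# trials a recollection process with probability
# rec_base * ((1 + lag) / (1 + lag_ref))^(-rec_decay) retrieves the study
# episode and produces the correct response (repeat -> "old"; lure ->
# "similar" under OSN, "new" under ON) regardless of familiarity; this
# dual-process term is what lets short-lag designs raise the LDI rather
# than merely pushing hard lures past the "old" criterion.  Finally a lapse
# replaces the response with a uniform draw over the prompt's options.

#' Participant-level generative parameters
#'
#' @param d_rep Target memory strength for a true repetition at the
#'   reference lag, in standardized (z) units.
#' @param bin_similarity Fraction of `d_rep` evoked by a lure from each
#'   difficulty bin (length 5, non-increasing; bin 1 = most similar).
#' @param c_old Familiarity criterion for responding "old".
#' @param c_sim Criterion separating "similar" from "new" (OSN only;
#'   must lie below `c_old`).
#' @param lapse_rate Probability of a uniform random response (at most 0.2).
#' @param lag_decay Exponent of the log-lag decay of `d_rep`.
#' @param lag_ref Reference lag (trials) at which `d_rep` applies.
#' @param rec_base Recollection probability at the reference lag.
#' @param rec_decay Exponent of the log-lag decay of recollection.
#' @return A list of class `mst_participant`.
#' @export
participant_params <- function(d_rep = 2.75,
                               bin_similarity = c(0.9, 0.75, 0.6, 0.45, 0.3),
                               c_old = 2.4, c_sim = 1.4, lapse_rate = 0.02,
                               lag_decay = 0.15, lag_ref = 160,
                               rec_base = 0.05, rec_decay = 0.8) {
  if (length(bin_similarity) != 5L || any(diff(bin_similarity) > 1e-12)) {
    stop0("`bin_similarity` must be 5 non-increasing fractions (bin 1 highest)")
  }
  if (any(bin_similarity < 0 | bin_similarity > 1)) {
    stop0("`bin_similarity` must lie in [0, 1]")
  }
  if (lapse_rate < 0 || lapse_rate > 0.2) stop0("`lapse_rate` must be in [0, 0.2]")
  if (c_sim >= c_old) stop0("`c_sim` must lie below `c_old`")
  if (rec_base < 0 || rec_base > 1) stop0("`rec_base` must be in [0, 1]")
  structure(list(d_rep = d_rep, bin_similarity = bin_similarity,
                 c_old = c_old, c_sim = c_sim, lapse_rate = lapse_rate,
                 lag_decay = lag_decay, lag_ref = lag_ref,
                 rec_base = rec_base, rec_decay = rec_decay),
            class = "mst_participant")
}

#' Cohort-level generative parameters
#'
#' Population distribution of [participant_params()] plus the
#' session-to-session structure: `retest_stability` is the correlation of a
#' participant's latent `d_rep` across sessions (1 = a perfectly stable
#' trait) and `practice_boost` is an additive `d_rep` increment applied
#' from the second session onward (an initial-session familiarization
#' effect).  The defaults emulate healthy young online participants whose
#' full-length baseline LDI averages roughly 0.28.
#'
#' @param mean_d_rep,sd_d_rep Population mean / SD of `d_rep`.
#' @param mean_c_old,sd_c_old Population mean / SD of `c_old`.
#' @param mean_c_sim,sd_c_sim Population mean / SD of `c_sim`.
#' @param mean_rec_base,sd_rec_base Population mean / SD of the
#'   recollection probability at the reference lag.  Recollection is the
#'   main stable individual-difference driver of lure discrimination, so
#'   `sd_rec_base` largely sets the population SD of the LDI.
#' @param bin_similarity Shared lure-bin similarity profile.
#' @param lapse_rate,lag_decay,lag_ref,rec_decay Shared participant
#'   parameters (see [participant_params()]).
#' @param retest_stability Across-session correlation of the latent
#'   participant abilities (`d_rep` and recollection), in `[0, 1]`.
#' @param practice_boost Additive `d_rep` increment from session 2 on.
#' @return A list of class `mst_cohort`.
#' @export
cohort_params <- function(mean_d_rep = 2.75, sd_d_rep = 0.8,
                          mean_c_old = 2.4, sd_c_old = 0.15,
                          mean_c_sim = 1.4, sd_c_sim = 0.15,
                          mean_rec_base = 0.05, sd_rec_base = 0.2,
                          bin_similarity = c(0.9, 0.75, 0.6, 0.45, 0.3),
                          lapse_rate = 0.02, lag_decay = 0.15, lag_ref = 160,
                          rec_decay = 0.8,
                          retest_stability = 0.85, practice_boost = 0.1) {
  if (retest_stability < 0 || retest_stability > 1) {
    stop0("`retest_stability` must be in [0, 1]")
  }
  if (sd_d_rep < 0 || sd_c_old < 0 || sd_c_sim < 0 || sd_rec_base < 0) {
    stop0("SDs must be >= 0")
  }
  structure(list(mean_d_rep = mean_d_rep, sd_d_rep = sd_d_rep,
                 mean_c_old = mean_c_old, sd_c_old = sd_c_old,
                 mean_c_sim = mean_c_sim, sd_c_sim = sd_c_sim,
                 mean_rec_base = mean_rec_base, sd_rec_base = sd_rec_base,
                 bin_similarity = bin_similarity, lapse_rate = lapse_rate,
                 lag_decay = lag_decay, lag_ref = lag_ref,
                 rec_decay = rec_decay,
                 retest_stability = retest_stability,
                 practice_boost = practice_boost),
            class = "mst_cohort")
}

# Lag factor ((1 + lag) / (1 + ref))^(-decay); 1 where lag is NA.
lag_factor <- function(lag, ref, decay) {
  out <- rep(1, length(lag))
  ok <- !is.na(lag)
  out[ok] <- ((1 + lag[ok]) / (1 + ref))^(-decay)
  out
}

# Per-trial retention lag: recorded lag for continuous probes; for
# study-test probes, the trial-index distance back to the study (or
# practice-study) presentation of the same pair.
probe_lags <- function(schedule) {
  tr <- schedule$trials
  lag <- as.numeric(tr$lag)
  probe <- tr$condition %in% c("repeat", "lure") & is.na(lag)
  if (any(probe)) {
    enc <- tr$condition == "study_target"
    enc_idx <- structure(tr$trial_index[enc],
                         names = pair_key(tr$set_id[enc], tr$pair_id[enc]))
    key <- pair_key(tr$set_id[probe], tr$pair_id[probe])
    lag[probe] <- tr$trial_index[probe] - unname(enc_idx[key])
  }
  lag
}

# Per-trial familiarity means and recollection probabilities.
trial_latents <- function(schedule, params) {
  tr <- schedule$trials
  lag <- probe_lags(schedule)
  mu <- numeric(nrow(tr))
  rp <- numeric(nrow(tr))
  probe <- tr$condition %in% c("repeat", "lure")
  d_eff <- params$d_rep * lag_factor(lag[probe], params$lag_ref, params$lag_decay)
  is_lure <- tr$condition[probe] == "lure"
  mu[probe] <- ifelse(is_lure,
                      d_eff * params$bin_similarity[tr$lure_bin[probe]],
                      d_eff)
  rp[probe] <- pmin(0.95, params$rec_base *
                      lag_factor(lag[probe], params$lag_ref, params$rec_decay))
  list(mu = mu, rec_p = rp)
}

#' Closed-form per-trial response probabilities
#'
#' The exact response distribution the simulator samples from, per scored
#' trial: normal-CDF familiarity probabilities mixed with the recollection
#' and lapse components.  Used as the analytic oracle for rate tests and by
#' [predicted_reliability()].
#'
#' @param schedule An `mst_schedule`.
#' @param params A [participant_params()].
#' @return A data.frame with one row per trial: `trial_index`, `condition`,
#'   `p_old`, `p_similar`, `p_new` (`p_similar` is 0 under the ON prompt).
#' @export
trial_response_probs <- function(schedule, params) {
  tr <- schedule$trials
  prompt <- schedule$design$prompt
  lat <- trial_latents(schedule, params)
  p_old_f <- 1 - stats::pnorm(params$c_old - lat$mu)
  p_sim_f <- if (prompt == "OSN") {
    stats::pnorm(params$c_old - lat$mu) - stats::pnorm(params$c_sim - lat$mu)
  } else {
    numeric(nrow(tr))
  }
  p_new_f <- 1 - p_old_f - p_sim_f
  r <- lat$rec_p
  is_rep <- tr$condition == "repeat"
  is_lure <- tr$condition == "lure"
  p_old <- (1 - r) * p_old_f + r * is_rep
  if (prompt == "OSN") {
    p_sim <- (1 - r) * p_sim_f + r * is_lure
  } else {
    p_sim <- numeric(nrow(tr))
  }
  p_new <- 1 - p_old - p_sim
  k <- if (prompt == "OSN") 3 else 2
  lam <- params$lapse_rate
  p_old <- (1 - lam) * p_old + lam / k
  p_sim <- if (prompt == "OSN") (1 - lam) * p_sim + lam / k else p_sim
  p_new <- 1 - p_old - p_sim
  data.frame(trial_index = tr$trial_index, condition = tr$condition,
             p_old = p_old, p_similar = p_sim, p_new = p_new)
}

#' Simulate one session
#'
#' Draws a familiarity value per trial from the generative model and
#' applies the criterion rule for the schedule's prompt, with recollection
#' and lapse components (see the module description).  Guided practice
#' trials are forced correct.  Study-phase trials carry no old/similar/new
#' decision and are logged as omissions.  Reproducible given the seed; with
#' a fixed seed the familiarity draws (and hence the "old" decisions) are
#' identical across the OSN and ON prompts.
#'
#' @param schedule An `mst_schedule`.
#' @param params A [participant_params()].
#' @param seed Integer seed.
#' @param participant,variant Metadata stamped on the log.
#' @return An `mst_response_log`.
#' @export
simulate_session <- function(schedule, params, seed = NULL,
                             participant = NA, variant = NULL) {
  stopifnot(inherits(schedule, "mst_schedule"))
  if (!inherits(params, "mst_participant")) {
    stop0("`params` must come from participant_params()")
  }
  tr <- schedule$trials
  prompt <- schedule$design$prompt
  n <- nrow(tr)
  lat <- trial_latents(schedule, params)
  with_seed(seed, {
    u_rec <- stats::runif(n)
    x <- stats::rnorm(n) + lat$mu
    u_lapse <- stats::runif(n)
    u_pick <- stats::runif(n)
    rt <- round(stats::rlnorm(n, meanlog = log(800), sdlog = 0.35))
    if (prompt == "OSN") {
      resp <- ifelse(x > params$c_old, "old",
                     ifelse(x > params$c_sim, "similar", "new"))
      opts <- c("old", "similar", "new")
    } else {
      resp <- ifelse(x > params$c_old, "old", "new")
      opts <- c("old", "new")
    }
    correct <- correct_response(tr$condition, prompt)
    recollect <- u_rec < lat$rec_p & tr$condition %in% c("repeat", "lure")
    resp[recollect] <- correct[recollect]
    lapse <- u_lapse < params$lapse_rate
    resp[lapse] <- opts[ceiling(u_pick[lapse] * length(opts))]
    guided <- tr$guided %in% TRUE & tr$phase == "practice_test"
    resp[guided] <- correct[guided]
    encoding <- tr$condition == "study_target"
    resp[encoding] <- "none"
    rt[encoding] <- NA_real_
    out <- tr
    out$response <- resp
    out$rt_ms <- rt
    response_log(out, participant = participant,
                 variant = variant %||% schedule$metadata$variant,
                 prompt = prompt)
  })
}

# Ideal response per condition under a prompt.
correct_response <- function(condition, prompt) {
  if (prompt == "OSN") {
    c(first = "new", foil = "new", "repeat" = "old", lure = "similar",
      study_target = "none")[condition]
  } else {
    c(first = "new", foil = "new", "repeat" = "old", lure = "new",
      study_target = "none")[condition]
  }
}

#' Draw correlated participant latents for a cohort
#'
#' The latent abilities (`d_rep` and the recollection base probability)
#' follow a trait-plus-state decomposition: with stability `rho`, session
#' `s` uses `mean + sd * (sqrt(rho) A_i + sqrt(1 - rho) E_is)` (plus the
#' practice boost on `d_rep` from session 2), so latents of any two
#' sessions correlate at `rho`.  Criteria are stable participant traits.
#'
#' @param cohort A [cohort_params()].
#' @param n Number of participants.
#' @param n_sessions Number of sessions.
#' @param seed Integer seed.
#' @return A list: `d_rep`, `rec_base` (`n x n_sessions` matrices),
#'   `c_old`, `c_sim` (vectors), and the shared scalar fields.
#' @export
draw_participants <- function(cohort, n, n_sessions = 2L, seed = NULL) {
  with_seed(seed, {
    rho <- cohort$retest_stability
    A_d <- stats::rnorm(n)
    A_r <- stats::rnorm(n)
    d <- rb <- matrix(0, n, n_sessions)
    for (s in seq_len(n_sessions)) {
      d[, s] <- cohort$mean_d_rep + cohort$practice_boost * (s >= 2) +
        cohort$sd_d_rep * (sqrt(rho) * A_d + sqrt(1 - rho) * stats::rnorm(n))
      rb[, s] <- cohort$mean_rec_base +
        cohort$sd_rec_base * (sqrt(rho) * A_r + sqrt(1 - rho) * stats::rnorm(n))
    }
    d <- pmax(d, 0.05)
    rb <- pmin(pmax(rb, 0), 0.95)
    c_old <- stats::rnorm(n, cohort$mean_c_old, cohort$sd_c_old)
    c_sim <- pmin(stats::rnorm(n, cohort$mean_c_sim, cohort$sd_c_sim),
                  c_old - 0.2)
    list(d_rep = d, rec_base = rb, c_old = c_old, c_sim = c_sim,
         bin_similarity = cohort$bin_similarity,
         lapse_rate = cohort$lapse_rate, lag_decay = cohort$lag_decay,
         lag_ref = cohort$lag_ref, rec_decay = cohort$rec_decay)
  })
}

participant_from_draw <- function(draw, i, s) {
  participant_params(d_rep = draw$d_rep[i, s],
                     bin_similarity = draw$bin_similarity,
                     c_old = draw$c_old[i], c_sim = draw$c_sim[i],
                     lapse_rate = draw$lapse_rate,
                     lag_decay = draw$lag_decay, lag_ref = draw$lag_ref,
                     rec_base = draw$rec_base[i, s],
                     rec_decay = draw$rec_decay)
}

#' Simulate a cohort over sessions
#'
#' Draws participant latents once (correlated across sessions at
#' `retest_stability`) and simulates every session.
#'
#' @param schedules One `mst_schedule` (reused every session) or a list of
#'   schedules, one per session.
#' @param cohort A [cohort_params()].
#' @param n_participants Number of participants.
#' @param n_sessions Number of sessions.
#' @param seed Integer seed.
#' @return A list: `logs` (list over participants of lists over sessions of
#'   response logs) and `draw` (the latents).
#' @export
simulate_cohort <- function(schedules, cohort, n_participants,
                            n_sessions = 2L, seed = NULL) {
  if (inherits(schedules, "mst_schedule")) {
    schedules <- rep(list(schedules), n_sessions)
  }
  stopifnot(length(schedules) == n_sessions)
  draw <- draw_participants(cohort, n_participants, n_sessions,
                            derive_seed(seed, 0L))
  logs <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    logs[[i]] <- vector("list", n_sessions)
    for (s in seq_len(n_sessions)) {
      logs[[i]][[s]] <- simulate_session(
        schedules[[s]], participant_from_draw(draw, i, s),
        seed = derive_seed(seed, i * 1000L + s), participant = i)
    }
  }
  list(logs = logs, draw = draw)
}

#' Semi-analytic predicted test-retest reliability of the LDI
#'
#' A Spearman-Brown-type attenuation oracle, computed without simulating
#' trial-level responses: participant latents are drawn from the cohort,
#' each participant-session's expected LDI and its binomial measurement
#' variance follow from the closed-form per-trial response probabilities
#' over the schedule's lure and foil trials, and the predicted correlation
#' is the covariance of expected scores over the square root of the product
#' of (true-score + measurement) variances.  With `apply_validity = TRUE`
#' the same REC validity screen as the scoring pipeline is applied (REC
#' observed with binomial noise must reach `rec_min` in both sessions)
#' before the moments are taken, mirroring the analysis pipeline.
#'
#' @param schedule An OSN `mst_schedule` (lure/foil structure is read from it).
#' @param cohort A [cohort_params()].
#' @param n_sim Number of simulated latent participants.
#' @param seed Integer seed.
#' @param apply_validity Apply the REC validity screen?
#' @param rec_min REC threshold when screening.
#' @return The predicted between-session correlation of observed LDI.
#' @export
predicted_reliability <- function(schedule, cohort, n_sim = 4000L,
                                  seed = NULL, apply_validity = FALSE,
                                  rec_min = mst_defaults()$rec_min) {
  tr <- schedule$trials
  scored <- !startsWith(tr$phase, "practice")
  lag <- probe_lags(schedule)[scored]
  cond <- tr$condition[scored]
  cond[cond == "first"] <- "foil"
  bin <- tr$lure_bin[scored]
  lure_t <- which(cond == "lure")
  rep_t <- which(cond == "repeat")
  n_foil <- sum(cond == "foil")
  n_rep <- length(rep_t)
  lam <- cohort$lapse_rate
  with_seed(seed, {
    draw <- draw_participants(cohort, n_sim, 2L)
    E <- V <- P_rec <- matrix(0, n_sim, 2L)
    lf_rec_lure <- lag_factor(lag[lure_t], cohort$lag_ref, cohort$rec_decay)
    lf_rec_rep <- lag_factor(lag[rep_t], cohort$lag_ref, cohort$rec_decay)
    for (s in 1:2) {
      d <- draw$d_rep[, s]
      lf_lure <- lag_factor(lag[lure_t], cohort$lag_ref, cohort$lag_decay)
      R_lure <- pmin(0.95, outer(draw$rec_base[, s], lf_rec_lure))
      mu_lure <- outer(d, lf_lure) *
        rep(cohort$bin_similarity[bin[lure_t]], each = n_sim)
      p_sim_f <- stats::pnorm(draw$c_old - mu_lure) -
        stats::pnorm(draw$c_sim - mu_lure)
      p_sim_l <- p_sim_f * (1 - R_lure) + R_lure
      p_sim_l <- (1 - lam) * p_sim_l + lam / 3
      p_sim_foil <- (1 - lam) *
        (stats::pnorm(draw$c_old) - stats::pnorm(draw$c_sim)) + lam / 3
      nl <- length(lure_t)
      E[, s] <- rowMeans(p_sim_l) - p_sim_foil
      V[, s] <- rowSums(p_sim_l * (1 - p_sim_l)) / nl^2 +
        p_sim_foil * (1 - p_sim_foil) / n_foil
      if (apply_validity) {
        lf_rep <- lag_factor(lag[rep_t], cohort$lag_ref, cohort$lag_decay)
        R_rep <- pmin(0.95, outer(draw$rec_base[, s], lf_rec_rep))
        mu_rep <- outer(d, lf_rep)
        p_old_r <- 1 - stats::pnorm(draw$c_old - mu_rep)
        p_old_r <- p_old_r * (1 - R_rep) + R_rep
        p_old_r <- (1 - lam) * p_old_r + lam / 3
        p_old_foil <- (1 - lam) * (1 - stats::pnorm(draw$c_old)) + lam / 3
        hit <- stats::rbinom(n_sim, n_rep,
                             pmin(1, rowMeans(p_old_r))) / n_rep
        fa <- stats::rbinom(n_sim, n_foil, pmin(1, p_old_foil)) / n_foil
        P_rec[, s] <- hit - fa
      }
    }
    keep <- if (apply_validity) P_rec[, 1] >= rec_min & P_rec[, 2] >= rec_min
            else rep(TRUE, n_sim)
    E <- E[keep, , drop = FALSE]
    V <- V[keep, , drop = FALSE]
    stats::cov(E[, 1], E[, 2]) /
      sqrt((stats::var(E[, 1]) + mean(V[, 1])) *
             (stats::var(E[, 2]) + mean(V[, 2])))
  })
}

#' Tune retest stability to a target predicted reliability
#'
#' Solves for the `retest_stability` at which
#' [predicted_reliability()] equals `target_r` (monotone in the stability),
#' holding every other cohort parameter fixed.
#'
#' @param target_r Target predicted reliability.
#' @param schedule Schedule passed to the oracle.
#' @param cohort Base cohort.
#' @param n_sim,seed,apply_validity Passed to [predicted_reliability()].
#' @return The cohort with `retest_stability` set to the solution.
#' @export
tune_stability <- function(target_r, schedule, cohort = cohort_params(),
                           n_sim = 4000L, seed = 1L, apply_validity = FALSE) {
  f <- function(rho) {
    ch <- cohort
    ch$retest_stability <- rho
    predicted_reliability(schedule, ch, n_sim = n_sim, seed = seed,
                          apply_validity = apply_validity) - target_r
  }
  hi <- f(0.999)
  if (hi < 0) {
    stop0("target reliability ", target_r, " exceeds the attainable maximum ",
          round(hi + target_r, 3), " for this design")
  }
  rho <- stats::uniroot(f, c(0.02, 0.999), tol = 1e-4)$root
  cohort$retest_stability <- rho
  cohort
}
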