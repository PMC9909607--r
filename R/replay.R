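# End-to-end replays of the task-optimization experiments on synthetic
# cohorts, and the offline fixture generator.

replay_table <- function() {
  list(
    "1" = list(variant = "full-st", prompt = "OSN", practice = FALSE),
    "2" = list(variant = "full-cont", prompt = "OSN", practice = FALSE),
    "3" = list(variant = "full-st", prompt = "ON", practice = FALSE),
    "4" = list(variant = "full-cont", prompt = "ON", practice = FALSE),
    "5a" = list(variant = "reduced-st", prompt = "OSN", practice = FALSE),
    "5b" = list(variant = "reduced-cont", prompt = "OSN", practice = FALSE),
    "6a" = list(variant = "reduced-st", prompt = "OSN", practice = TRUE),
    "6b" = list(variant = "reduced-cont", prompt = "OSN", practice = TRUE),
    "7" = list(variant = "reduced-cont", prompt = "OSN", practice = TRUE,
               older = TRUE)
  )
}

#' Replay one optimization experiment on a synthetic cohort
#'
#' Wires the full pipeline -- schedule generation, cohort simulation,
#' scoring, validity filtering, robust correlation, and the Fisher r-to-z
#' comparison against a reference reliability -- for the design pair of
#' each experiment in the optimization series: 1 baseline vs. baseline
#' (test-retest), 2 continuous format, 3 old/new prompt, 4 both, 5a/5b
#' reduced study-test / continuous, 6a/6b the reduced variants with guided
#' practice, 7 the reduced continuous variant in an older cohort, and 8
#' four weekly half-set sessions under repeat / no-repeat stimulus reuse.
#' Statistics are computed on synthetic participants, so they replay the
#' *pipeline*, not the human data.
#'
#' @param experiment_id One of `"1" ... "7"`, `"5a"`, `"5b"`, `"6a"`,
#'   `"6b"`, `"8"` (`"5"` and `"6"` resolve to their `a` halves).
#' @param cohort A [cohort_params()]; default is the young-adult cohort,
#'   or an illustrative lower-memory-strength cohort for experiment 7.
#' @param n_participants Cohort size (experiment 8 splits it over the two
#'   stimulus-reuse groups).
#' @param seed Integer seed.
#' @param reference Reference correlation for the Fisher comparison
#'   (list with `r` and `n`).
#' @param bank Stimulus bank; a canonical synthetic bank by default.
#' @return For experiments 1-7: a list with the paired scores, robust fit,
#'   `r_clean`, valid / removed counts, and the Fisher test.  For
#'   experiment 8: per-group long-format session scores and session means.
#' @export
experiment_replay <- function(experiment_id, cohort = NULL,
                              n_participants = 40L, seed = 1L,
                              reference = list(r = 0.73, n = 46L),
                              bank = NULL) {
  experiment_id <- as.character(experiment_id)
  if (experiment_id %in% c("5", "6")) {
    experiment_id <- paste0(experiment_id, "a")
  }
  bank <- bank %||% make_synthetic_bank(seed = derive_seed(seed, 99L))
  if (experiment_id == "8") {
    return(replay_repeat_testing(cohort %||% cohort_params(), n_participants,
                                 seed, bank))
  }
  info <- replay_table()[[experiment_id]]
  if (is.null(info)) stop0("unknown experiment id '", experiment_id, "'")
  if (is.null(cohort)) {
    cohort <- if (isTRUE(info$older)) cohort_params(mean_d_rep = 2.2)
              else cohort_params()
  }
  base_spec <- mst_variant_spec("full-st", "OSN",
                                seed = derive_seed(seed, 1L))
  var_spec <- mst_variant_spec(info$variant, info$prompt,
                               practice = isTRUE(info$practice),
                               seed = derive_seed(seed, 2L))
  set1 <- bank[bank$set_id == 1L, , drop = FALSE]
  set2 <- bank[bank$set_id == 2L, , drop = FALSE]
  draw <- draw_participants(cohort, n_participants, 2L, derive_seed(seed, 3L))
  rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    base_first <- i %% 2L == 1L # counterbalanced task order
    sets <- if (i %/% 2L %% 2L == 0L) list(set1, set2) else list(set2, set1)
    base_spec$seed <- derive_seed(seed, 10L + 4L * i)
    var_spec$seed <- derive_seed(seed, 11L + 4L * i)
    base_sched <- build_study_test(base_spec, sets[[1L]])
    var_sched <- build_schedule(var_spec, sets[[2L]])
    s_base <- if (base_first) 1L else 2L
    s_var <- 3L - s_base
    log_b <- simulate_session(base_sched, participant_from_draw(draw, i, s_base),
                              seed = derive_seed(seed, 12L + 4L * i),
                              participant = i)
    log_v <- simulate_session(var_sched, participant_from_draw(draw, i, s_var),
                              seed = derive_seed(seed, 13L + 4L * i),
                              participant = i)
    rp_b <- score_session(log_b)
    rp_v <- score_session(log_v)
    rows[[i]] <- data.frame(
      participant = i, base_first = base_first,
      baseline = rp_b$ldi,
      variant = if (info$prompt == "OSN") rp_v$ldi else rp_v$dprime_tl,
      valid = rp_b$valid && rp_v$valid)
  }
  scores <- do.call(rbind, rows)
  valid <- scores[scores$valid, , drop = FALSE]
  if (nrow(valid) < 5L) stop0("fewer than 5 valid synthetic sessions")
  fit <- robust_fit_with_outliers(valid[c("baseline", "variant")])
  n_clean <- fit$n - fit$n_removed
  fisher <- fisher_compare(fit$r_clean, n_clean, reference$r, reference$n)
  structure(list(experiment = experiment_id, variant = info$variant,
                 prompt = info$prompt, cohort = cohort,
                 scores = scores, n_enrolled = n_participants,
                 n_valid = nrow(valid), n_removed = fit$n_removed,
                 fit = fit, r_clean = fit$r_clean,
                 mean_baseline = mean(valid$baseline),
                 mean_variant = mean(valid$variant),
                 fisher_vs_reference = fisher, reference = reference),
            class = "mst_replay")
}

#' @export
print.mst_replay <- function(x, ...) {
  cat("Experiment", x$experiment, "replay:", x$variant, "/", x$prompt, "\n")
  cat(sprintf("  %d enrolled, %d valid, %d outlier(s) removed\n",
              x$n_enrolled, x$n_valid, x$n_removed))
  cat(sprintf("  baseline mean %.3f | variant mean %.3f | r = %.3f\n",
              x$mean_baseline, x$mean_variant, x$r_clean))
  cat(sprintf("  Fisher one-tailed p = %.3f vs. reference r = %.2f (n = %d)\n",
              x$fisher_vs_reference$p, x$reference$r, x$reference$n))
  invisible(x)
}

# Four weekly half-set study-test sessions; half the cohort re-uses the
# identical half-set on sessions (1,2) and (3,4), the rest sees four
# distinct difficulty-matched halves.
replay_repeat_testing <- function(cohort, n_participants, seed, bank) {
  n_rep <- n_participants %/% 2L
  n_nor <- n_participants - n_rep
  half_spec <- design_spec("study_test", "OSN", n_repeat = 32L, n_lure = 32L,
                           n_foil = 32L, label = "half-st")
  halves <- list()
  for (s in unique(bank$set_id)) {
    h <- split_matched_halves(bank[bank$set_id == s, , drop = FALSE],
                              seed = derive_seed(seed, 200L + s))
    halves[[paste0(s, "a")]] <- h$half_a
    halves[[paste0(s, "b")]] <- h$half_b
  }
  run_group <- function(group, n, mode, seed_off) {
    plan <- plan_sessions(n, "half-st", sets_available = 1:5, mode = mode,
                          seed = derive_seed(seed, seed_off))
    draw <- draw_participants(cohort, n, 4L, derive_seed(seed, seed_off + 1L))
    out <- vector("list", n * 4L)
    k <- 0L
    for (i in seq_len(n)) {
      built <- list() # identical stimulus label -> identical schedule
      for (s in 1:4) {
        lab <- plan$stim_label[plan$participant == i & plan$session == s]
        if (is.null(built[[lab]])) {
          half_spec$seed <- derive_seed(seed, seed_off + 10L * i + s)
          built[[lab]] <- build_study_test(half_spec, halves[[lab]])
        }
        log <- simulate_session(built[[lab]],
                                participant_from_draw(draw, i, s),
                                seed = derive_seed(seed,
                                                   seed_off + 1000L + 10L * i + s),
                                participant = paste0(group, i))
        rp <- score_session(log)
        k <- k + 1L
        out[[k]] <- data.frame(group = group, participant = paste0(group, i),
                               session = s, stim_label = lab,
                               ldi = rp$ldi, rec = rp$rec, valid = rp$valid)
      }
    }
    do.call(rbind, out)
  }
  sess <- rbind(run_group("repeat", n_rep, "repeat", 300L),
                run_group("no_repeat", n_nor, "no_repeat", 400L))
  valid <- sess[sess$valid, , drop = FALSE]
  means <- aggregate(cbind(ldi, rec) ~ group + session, valid, mean)
  long <- do.call(rbind, lapply(c("ldi", "rec"), function(m) {
    data.frame(participant = valid$participant, session = valid$session,
               variant = "half-st", group = valid$group, metric = m,
               value = valid[[m]])
  }))
  structure(list(experiment = "8", sessions = sess, long = long,
                 session_means = means,
                 n_valid_sessions = nrow(valid)),
            class = "mst_replay8")
}

#' @export
print.mst_replay8 <- function(x, ...) {
  cat("Experiment 8 replay:", x$n_valid_sessions, "valid sessions\n")
  print(x$session_means)
  invisible(x)
}

#' Generate the offline fixture bundle
#'
#' Writes, under `dir`: the canonical synthetic bank (`bank.csv`), one
#' schedule per task variant (`schedule-<variant>.csv` + design JSON), and
#' simulated response logs for a young-like and a low-performing cohort
#' (`log-<cohort>-p<participant>.csv`).  Regenerates bit-identically from
#' the same seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_logs Logs per cohort.
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, n_logs = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bank <- make_synthetic_bank(seed = derive_seed(seed, 1L))
  paths <- file.path(dir, "bank.csv")
  write_bank(bank, paths[1L])
  set1 <- bank[bank$set_id == 1L, ]
  scheds <- list()
  for (v in c("full-st", "full-cont", "reduced-st", "reduced-cont")) {
    spec <- mst_variant_spec(v, "OSN", practice = grepl("reduced", v),
                             seed = derive_seed(seed, 2L + match(v, c(
                               "full-st", "full-cont", "reduced-st",
                               "reduced-cont"))))
    scheds[[v]] <- build_schedule(spec, set1)
    csv <- file.path(dir, paste0("schedule-", v, ".csv"))
    js <- file.path(dir, paste0("schedule-", v, ".json"))
    write_schedule(scheds[[v]], csv, js)
    paths <- c(paths, csv, js)
  }
  cohorts <- list(young = cohort_params(),
                  low_performing = cohort_params(mean_d_rep = 1.3))
  for (cn in names(cohorts)) {
    draw <- draw_participants(cohorts[[cn]], n_logs, 1L,
                              derive_seed(seed, 50L + match(cn, names(cohorts))))
    for (i in seq_len(n_logs)) {
      log <- simulate_session(scheds[["reduced-cont"]],
                              participant_from_draw(draw, i, 1L),
                              seed = derive_seed(seed, 100L + 10L *
                                                   match(cn, names(cohorts)) + i),
                              participant = paste0(cn, "-", i))
      p <- file.path(dir, sprintf("log-%s-p%d.csv", cn, i))
      write_response_log(log, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
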