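# Trial-schedule generation for every task variant: study-test and
# continuous formats, full and reduced lengths, guided practice blocks,
# lag-banded continuous placement, and session counterbalancing.
#
# A schedule is a list (class `mst_schedule`) with elements:
#   design   -- the mst_design it realizes
#   trials   -- data.frame: trial_index, phase, condition, set_id, pair_id,
#               exemplar, lure_bin, lag, guided
#   metadata -- variant label and the stimulus sets used
#
# Exemplar convention: the first/study presentation shows exemplar "a"; the
# lure probe shows exemplar "b" of the same pair; repeats re-show "a".

trial_cols <- function(phase, condition, pairs, exemplar, lag, guided) {
  if (nrow(pairs) == 0L) return(NULL)
  data.frame(phase = phase, condition = condition,
             set_id = pairs$set_id, pair_id = pairs$pair_id,
             exemplar = exemplar, lure_bin = pairs$lure_bin,
             lag = as.integer(lag), guided = guided)
}

finish_schedule <- function(spec, parts) {
  trials <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  trials <- cbind(trial_index = seq_len(nrow(trials)), trials)
  rownames(trials) <- NULL
  structure(list(design = spec, trials = trials,
                 metadata = list(variant = spec$label %||% spec$format,
                                 sets_used = sort(unique(trials$set_id)))),
            class = "mst_schedule")
}

#' @export
print.mst_schedule <- function(x, ...) {
  tr <- x$trials
  cat("MST schedule:", x$metadata$variant, "/", x$design$prompt, "-",
      nrow(tr), "trials\n")
  print(table(tr$phase, tr$condition))
  invisible(x)
}

# How many stimulus pairs a practice block consumes.
practice_pairs_needed <- function(practice) {
  if (is.null(practice)) return(0L)
  if (practice$format == "study_test") {
    n_test <- practice$n_guided + practice$n_unguided
    alloc <- practice_test_alloc(practice)
    practice$n_study + alloc["foil"]
  } else {
    n <- practice$n_guided + practice$n_unguided
    alloc <- practice_cont_alloc(n)
    alloc["first"]
  }
}

# Practice test-phase allocation (study-test): near-equal thirds, with
# repeats + lures capped by the number of practice study trials.
practice_test_alloc <- function(practice) {
  n_test <- practice$n_guided + practice$n_unguided
  n_rep <- n_test %/% 3L
  n_lure <- n_test %/% 3L
  if (n_rep + n_lure > practice$n_study) {
    stop0("practice block needs at least ", n_rep + n_lure, " study trials")
  }
  c(rep = n_rep, lure = n_lure, foil = n_test - n_rep - n_lure)
}

# Practice continuous allocation: a quarter each of repeats and lures, the
# rest first presentations (9 trials -> 5 firsts / 2 repeats / 2 lures).
practice_cont_alloc <- function(n) {
  n_rep <- n %/% 4L
  n_lure <- n %/% 4L
  c(first = n - n_rep - n_lure, rep = n_rep, lure = n_lure)
}

#' Build a guided practice block
#'
#' Constructs the practice trials for one task format from a reserved pool
#' of pairs that is never reused in the scored block.  Guided trials (where
#' the correct answer is forced) come first within the practice test block.
#'
#' @param practice A [practice_spec()].
#' @param pairs Reserved stimulus pairs (at least
#'   the number consumed by the block).
#' @param seed Integer seed.
#' @return A trials data.frame with phases `practice_study` /
#'   `practice_test`.
#' @export
build_practice <- function(practice, pairs, seed = NULL) {
  stopifnot(inherits(practice, "mst_practice"))
  pairs <- as.data.frame(pairs)
  np <- practice_pairs_needed(practice)
  if (nrow(pairs) < np) stop0("practice block needs ", np, " pairs")
  with_seed(seed, {
    pairs <- pairs[sample.int(nrow(pairs), np), , drop = FALSE]
    if (practice$format == "study_test") {
      alloc <- practice_test_alloc(practice)
      studied <- pairs[seq_len(practice$n_study), , drop = FALSE]
      foils <- pairs[practice$n_study + seq_len(alloc["foil"]), , drop = FALSE]
      study <- trial_cols("practice_study", "study_target", studied, "a", NA, TRUE)
      test_p <- rbind(
        trial_cols("practice_test", "repeat",
                   studied[seq_len(alloc["rep"]), , drop = FALSE], "a", NA, FALSE),
        trial_cols("practice_test", "lure",
                   studied[alloc["rep"] + seq_len(alloc["lure"]), , drop = FALSE],
                   "b", NA, FALSE),
        trial_cols("practice_test", "foil", foils, "a", NA, FALSE))
      test_p <- test_p[sample.int(nrow(test_p)), , drop = FALSE]
      test_p$guided <- seq_len(nrow(test_p)) <= practice$n_guided
      rbind(study, test_p)
    } else {
      n <- practice$n_guided + practice$n_unguided
      alloc <- practice_cont_alloc(n)
      firsts <- pairs
      block <- trial_cols("practice_test", "first", firsts, "a", NA, FALSE)
      # probes follow the firsts, probing the earliest firsts in order
      probe_of <- seq_len(alloc["rep"] + alloc["lure"])
      cond <- rep(c("repeat", "lure"), c(alloc["rep"], alloc["lure"]))
      probes <- trial_cols("practice_test", cond,
                           firsts[probe_of, , drop = FALSE],
                           ifelse(cond == "lure", "b", "a"), NA, FALSE)
      out <- rbind(block, probes)
      out$lag[nrow(block) + seq_along(probe_of)] <-
        (nrow(block) + seq_along(probe_of)) - probe_of
      out$guided <- seq_len(nrow(out)) <= practice$n_guided
      out
    }
  })
}

#' Build a study-test schedule
#'
#' Draws the needed pairs from `pairs`, shows every later-tested repeat and
#' lure target once in a shuffled incidental-encoding (study) phase, then a
#' shuffled test phase mixing true repetitions (exemplar a), similar lures
#' (exemplar b), and novel foils.  The full-length design (64/64/64) yields
#' 128 study + 192 test = 320 trials; the reduced design (20/44/20) yields
#' 64 study + 84 test = 148 trials.
#'
#' @param spec A study-test [design_spec()].
#' @param pairs Stimulus pairs to draw from (e.g. one bank set).
#' @return An `mst_schedule`.
#' @export
#' @examples
#' bank <- make_synthetic_bank(seed = 1)
#' sched <- build_study_test(mst_variant_spec("full-st", seed = 2),
#'                           bank[bank$set_id == 1, ])
#' nrow(sched$trials) # 320
build_study_test <- function(spec, pairs) {
  stopifnot(inherits(spec, "mst_design"))
  if (spec$format != "study_test") stop0("`spec` must be a study_test design")
  pairs <- as.data.frame(pairs)
  validate_bank(pairs)
  n_need <- spec$n_repeat + spec$n_lure + spec$n_foil
  with_seed(spec$seed, {
    pool <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    practice_trials <- NULL
    if (!is.null(spec$practice)) {
      np <- practice_pairs_needed(spec$practice)
      if (nrow(pool) < n_need + np) {
        stop0("insufficient pairs: need ", n_need + np, " (incl. practice), have ",
              nrow(pool))
      }
      practice_trials <- build_practice(spec$practice,
                                        pool[seq_len(np), , drop = FALSE])
      pool <- pool[-seq_len(np), , drop = FALSE]
    }
    if (nrow(pool) < n_need) {
      stop0("insufficient pairs: need ", n_need, ", have ", nrow(pool))
    }
    rep_p <- pool[seq_len(spec$n_repeat), , drop = FALSE]
    lure_p <- pool[spec$n_repeat + seq_len(spec$n_lure), , drop = FALSE]
    foil_p <- pool[spec$n_repeat + spec$n_lure + seq_len(spec$n_foil), ,
                   drop = FALSE]
    study_p <- rbind(rep_p, lure_p)
    study_p <- study_p[sample.int(nrow(study_p)), , drop = FALSE]
    study <- trial_cols("study", "study_target", study_p, "a", NA, FALSE)
    test <- rbind(trial_cols("test", "repeat", rep_p, "a", NA, FALSE),
                  trial_cols("test", "lure", lure_p, "b", NA, FALSE),
                  trial_cols("test", "foil", foil_p, "a", NA, FALSE))
    test <- test[sample.int(nrow(test)), , drop = FALSE]
    parts <- list(
      practice_trials[practice_trials$phase == "practice_study", , drop = FALSE],
      study,
      practice_trials[practice_trials$phase == "practice_test", , drop = FALSE],
      test)
    finish_schedule(spec, parts)
  })
}

# Randomized greedy placement of probes at lag-banded gaps.  Narrow bands
# are placed first (while the board is empty); for each probe the allowed
# lags are tried in random order and a uniformly random feasible slot pair
# is taken.  A dead end restarts the whole placement; restarts are bounded
# by `max_attempts` (the dense full-length design typically needs a few
# dozen).
place_probes <- function(n_slots, lo, hi, max_attempts = 10000L) {
  n_probe <- length(lo)
  ord <- order(hi - lo)
  last_fail <- NULL
  for (attempt in seq_len(max_attempts)) {
    free <- rep(TRUE, n_slots)
    fp <- pp <- integer(n_probe)
    ok <- TRUE
    for (j in ord) {
      placed <- FALSE
      lags <- lo[j]:hi[j]
      for (lag in lags[sample.int(length(lags))]) {
        if (lag >= n_slots) next
        cand <- which(free[seq_len(n_slots - lag)] & free[(1L + lag):n_slots])
        if (length(cand)) {
          p <- cand[sample.int(length(cand), 1L)]
          fp[j] <- p
          pp[j] <- p + lag
          free[c(p, p + lag)] <- FALSE
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        ok <- FALSE
        last_fail <- c(lo[j], hi[j])
        break
      }
    }
    if (ok) return(list(first = fp, probe = pp, leftover = which(free)))
  }
  stop0("continuous placement failed after ", max_attempts,
        " restarts; could not satisfy lag band [", last_fail[1L], ",",
        last_fail[2L], "]")
}

#' Build a continuous schedule
#'
#' Generates a single interleaved block in which every repeat or lure probe
#' has its first presentation earlier in the block at a gap (lag, in trials)
#' drawn from the design's lag bands, with band membership counts met
#' exactly.  First presentations double as the novel foils.  The full-length
#' design (128 firsts / 64 repeats / 64 lures, 32 probes per band per
#' condition) yields 256 trials; the reduced design (64/20/44) yields 128.
#'
#' @param spec A continuous [design_spec()].
#' @param pairs Stimulus pairs to draw from.
#' @param max_attempts Bound on probe-placement attempts before erroring.
#' @return An `mst_schedule`.
#' @export
build_continuous <- function(spec, pairs, max_attempts = 10000L) {
  stopifnot(inherits(spec, "mst_design"))
  if (spec$format != "continuous") stop0("`spec` must be a continuous design")
  pairs <- as.data.frame(pairs)
  validate_bank(pairs)
  bands <- spec$lag_bands
  probe_cond <- c(rep("repeat", spec$n_repeat), rep("lure", spec$n_lure))
  probe_lo <- c(rep(bands$lo, bands$n_repeat), rep(bands$lo, bands$n_lure))
  probe_hi <- c(rep(bands$hi, bands$n_repeat), rep(bands$hi, bands$n_lure))
  n_probe <- length(probe_cond)
  n_slots <- spec$n_first + n_probe
  with_seed(spec$seed, {
    pool <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    practice_trials <- NULL
    if (!is.null(spec$practice)) {
      np <- practice_pairs_needed(spec$practice)
      if (nrow(pool) < spec$n_first + np) {
        stop0("insufficient pairs: need ", spec$n_first + np,
              " (incl. practice), have ", nrow(pool))
      }
      practice_trials <- build_practice(spec$practice,
                                        pool[seq_len(np), , drop = FALSE])
      pool <- pool[-seq_len(np), , drop = FALSE]
    }
    if (nrow(pool) < spec$n_first) {
      stop0("insufficient pairs: need ", spec$n_first, ", have ", nrow(pool))
    }
    placement <- place_probes(n_slots, probe_lo, probe_hi, max_attempts)
    first_pos <- sort(c(placement$first, placement$leftover))
    stopifnot(length(first_pos) == spec$n_first)
    # the (already shuffled) pool maps onto first positions in order
    scored_pool <- pool[seq_len(spec$n_first), , drop = FALSE]
    pair_at <- integer(n_slots) # slot -> row of scored_pool (firsts only)
    pair_at[first_pos] <- seq_len(spec$n_first)
    cond <- rep("first", n_slots)
    exem <- rep("a", n_slots)
    lag <- rep(NA_integer_, n_slots)
    cond[placement$probe] <- probe_cond
    exem[placement$probe] <- ifelse(probe_cond == "lure", "b", "a")
    lag[placement$probe] <- placement$probe - placement$first
    pair_row <- pair_at
    pair_row[placement$probe] <- pair_at[placement$first]
    block <- trial_cols("continuous", cond,
                        scored_pool[pair_row, , drop = FALSE], exem, lag, FALSE)
    finish_schedule(spec, list(practice_trials, block))
  })
}

#' Build a schedule for any design
#'
#' Dispatches to [build_study_test()] or [build_continuous()] on the
#' design's format.
#'
#' @param spec An [design_spec()].
#' @param pairs Stimulus pairs.
#' @param ... Passed on to the format-specific builder.
#' @return An `mst_schedule`.
#' @export
build_schedule <- function(spec, pairs, ...) {
  if (spec$format == "study_test") build_study_test(spec, pairs)
  else build_continuous(spec, pairs, ...)
}

#' Independently check a schedule against its design
#'
#' Re-derives condition counts, pair-usage uniqueness, study coverage, lag
#' values, and lag-band membership directly from the raw trial list, without
#' using any generator state, and compares them with the declared design.
#'
#' @param schedule An `mst_schedule`.
#' @return A list with `valid` (logical) and `problems`
#'   (character vector, empty when valid).
#' @export
validate_schedule <- function(schedule) {
  d <- schedule$design
  tr <- schedule$trials
  problems <- character()
  note <- function(...) problems[[length(problems) + 1L]] <<- paste0(...)
  if (!identical(tr$trial_index, seq_len(nrow(tr)))) {
    note("trial_index is not 1..n in order")
  }
  practice <- tr[startsWith(tr$phase, "practice"), , drop = FALSE]
  scored <- tr[!startsWith(tr$phase, "practice"), , drop = FALSE]
  pk <- pair_key(scored$set_id, scored$pair_id)
  if (nrow(practice) &&
      any(pair_key(practice$set_id, practice$pair_id) %in% pk)) {
    note("practice stimuli reused in the scored block")
  }
  if (!is.null(d$practice)) {
    n_prac <- if (d$format == "study_test") {
      d$practice$n_study + d$practice$n_guided + d$practice$n_unguided
    } else {
      d$practice$n_guided + d$practice$n_unguided
    }
    if (nrow(practice) != n_prac) {
      note("practice block has ", nrow(practice), " trials, expected ", n_prac)
    }
    if (sum(practice$guided) <
        d$practice$n_guided + (d$practice$n_study %||% 0L)) {
      note("guided practice trials fewer than specified")
    }
  }
  cnt <- function(cond) sum(scored$condition == cond)
  if (d$format == "study_test") {
    study <- scored[scored$phase == "study", , drop = FALSE]
    test <- scored[scored$phase == "test", , drop = FALSE]
    if (nrow(study) != d$n_study) {
      note("study phase has ", nrow(study), " trials, expected ", d$n_study)
    }
    for (co in c("repeat", "lure", "foil")) {
      n_exp <- d[[paste0("n_", sub("repeat", "repeat", co))]]
      n_exp <- switch(co, "repeat" = d$n_repeat, lure = d$n_lure, foil = d$n_foil)
      if (sum(test$condition == co) != n_exp) {
        note("test phase has ", sum(test$condition == co), " ", co,
             " trials, expected ", n_exp)
      }
    }
    sk <- pair_key(study$set_id, study$pair_id)
    if (anyDuplicated(sk)) note("a pair is studied more than once")
    tk <- pair_key(test$set_id, test$pair_id)
    if (anyDuplicated(tk)) note("a pair is tested in more than one condition")
    old_k <- tk[test$condition %in% c("repeat", "lure")]
    if (!all(old_k %in% sk)) note("a tested repeat/lure was never studied")
    foil_k <- tk[test$condition == "foil"]
    if (any(foil_k %in% sk)) note("a foil pair was studied")
    if (any(test$exemplar[test$condition == "lure"] != "b")) {
      note("lure trials must present exemplar b")
    }
    if (any(test$exemplar[test$condition != "lure"] != "a") ||
        any(study$exemplar != "a")) {
      note("non-lure trials must present exemplar a")
    }
  } else {
    if (cnt("first") != d$n_first) {
      note("block has ", cnt("first"), " first presentations, expected ", d$n_first)
    }
    if (cnt("repeat") != d$n_repeat || cnt("lure") != d$n_lure) {
      note("probe counts ", cnt("repeat"), "/", cnt("lure"),
           " differ from design ", d$n_repeat, "/", d$n_lure)
    }
    first_idx <- structure(scored$trial_index[scored$condition == "first"],
                           names = pk[scored$condition == "first"])
    if (anyDuplicated(names(first_idx))) note("a pair is first-presented twice")
    probes <- scored[scored$condition %in% c("repeat", "lure"), , drop = FALSE]
    pks <- pair_key(probes$set_id, probes$pair_id)
    if (anyDuplicated(pks)) note("a pair is probed more than once")
    fi <- first_idx[pks]
    if (anyNA(fi)) {
      note("a probe has no first presentation")
    } else {
      real_lag <- probes$trial_index - unname(fi)
      if (any(real_lag <= 0)) note("a probe precedes its first presentation")
      if (!isTRUE(all(real_lag == probes$lag))) {
        note("recorded lag differs from trial-index difference")
      }
      # band tallies can only be checked when the design declares bands
      # (a design inferred from a bare CSV does not)
      for (b in seq_len(NROW(d$lag_bands))) {
        in_b <- probes$lag >= d$lag_bands$lo[b] & probes$lag <= d$lag_bands$hi[b]
        nr <- sum(in_b & probes$condition == "repeat")
        nl <- sum(in_b & probes$condition == "lure")
        if (nr != d$lag_bands$n_repeat[b] || nl != d$lag_bands$n_lure[b]) {
          note("band [", d$lag_bands$lo[b], ",", d$lag_bands$hi[b], "] holds ",
               nr, "/", nl, " repeat/lure probes, expected ",
               d$lag_bands$n_repeat[b], "/", d$lag_bands$n_lure[b])
        }
      }
    }
    if (any(probes$exemplar[probes$condition == "lure"] != "b") ||
        any(probes$exemplar[probes$condition == "repeat"] != "a")) {
      note("probe exemplars violate the a/b convention")
    }
  }
  list(valid = length(problems) == 0L, problems = problems)
}

#' Estimate schedule duration
#'
#' The minimum duration is the number of scored trials times the minimum
#' trial length; the expected duration replaces the per-trial minimum with
#' the assumed response latency whenever the latency exceeds that minimum
#' (trials are self-paced beyond the stimulus duration).
#'
#' @param schedule An `mst_schedule`.
#' @param timing A [timing_spec()]; defaults to the schedule's own.
#' @return Named numeric: `min_duration_s`, `expected_duration_s`.
#' @export
estimate_duration <- function(schedule, timing = NULL) {
  timing <- timing %||% schedule$design$timing
  scored <- !startsWith(schedule$trials$phase, "practice")
  n <- sum(scored)
  per_expected <- max(timing$min_trial_s, timing$assumed_response_latency_s)
  c(min_duration_s = n * timing$min_trial_s,
    expected_duration_s = n * per_expected)
}

#' Plan sessions across participants
#'
#' `counterbalanced_order` rotates the order of the given variants across
#' participants (each order occurs within one of equally often) and rotates
#' which stimulus set serves which variant.  `repeat` and `no_repeat` plan
#' four half-set sessions of one variant: `repeat` reuses the same
#' difficulty-matched half on sessions (1,2) and (3,4) (e.g. 1a, 1a, 2a,
#' 2a), `no_repeat` uses four pairwise-distinct halves (e.g. 1a, 1b, 2a,
#' 2b); set choices rotate across participants.
#'
#' @param n_participants Number of participants.
#' @param variants Character vector of variant labels.
#' @param sets_available Integer ids of usable stimulus sets.
#' @param mode `"counterbalanced_order"`, `"repeat"`, or `"no_repeat"`.
#' @param seed Integer seed (shuffles participant-to-order assignment).
#' @return A data.frame: `participant`, `session`, `variant`, `set_id`,
#'   `half` (`NA` outside half-set modes), `stim_label`.
#' @export
plan_sessions <- function(n_participants, variants,
                          sets_available = 1:6,
                          mode = c("counterbalanced_order", "repeat",
                                   "no_repeat"),
                          seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_participants >= 1)
  with_seed(seed, {
    perm <- sample.int(n_participants)
    rows <- vector("list", n_participants)
    if (mode == "counterbalanced_order") {
      k <- length(variants)
      if (length(sets_available) < k) {
        stop0("need at least as many stimulus sets as variants")
      }
      for (i in seq_len(n_participants)) {
        slot <- which(perm == i) # balanced assignment of rotations
        rot <- (slot - 1L) %% k
        ord <- ((seq_len(k) - 1L + rot) %% k) + 1L
        set_rot <- (slot - 1L) %/% k %% k
        sets <- sets_available[((seq_len(k) - 1L + set_rot) %% k) + 1L]
        rows[[i]] <- data.frame(participant = i, session = seq_len(k),
                                variant = variants[ord],
                                set_id = sets[ord], half = NA_character_,
                                stim_label = as.character(sets[ord]))
      }
    } else {
      if (length(sets_available) < 2L) stop0("need at least two stimulus sets")
      n_sets <- length(sets_available)
      variant <- variants[1L]
      for (i in seq_len(n_participants)) {
        slot <- which(perm == i)
        s1 <- sets_available[((slot - 1L) %% n_sets) + 1L]
        s2 <- sets_available[(slot %% n_sets) + 1L]
        if (mode == "repeat") {
          half <- if (slot %% 2L == 0L) "a" else "b"
          sets <- c(s1, s1, s2, s2)
          halves <- rep(half, 4L)
        } else {
          sets <- c(s1, s1, s2, s2)
          halves <- c("a", "b", "a", "b")
        }
        rows[[i]] <- data.frame(participant = i, session = 1:4,
                                variant = variant, set_id = sets,
                                half = halves,
                                stim_label = paste0(sets, halves))
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
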