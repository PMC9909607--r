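# Design specifications: timing, practice blocks, and task-variant designs.

#' Package-wide default constants
#'
#' Central registry of the tunable constants used across the toolkit: the
#' validity thresholds (minimum corrected recognition for three-choice
#' sessions, minimum target/foil d-prime for two-choice sessions), the
#' outlier-detection false-discovery rate, trial-timing defaults, and the
#' default cross-variant score-conversion line.  Every value can be
#' overridden at the call site of the function that consumes it.
#'
#' @return A named list of defaults.
#' @export
mst_defaults <- function() {
  list(
    rec_min = 0.5,            # OSN validity: minimum REC
    dtf_min = 1.5,            # ON validity: minimum d'(TF)
    rout_q = 0.01,            # outlier FDR for robust regression
    similar_use_range = c(0.05, 0.90), # review flag on overall p("similar")
    stim_duration_s = 2.0,
    min_isi_s = 0.5,
    min_trial_s = 2.5,
    assumed_response_latency_s = 1.5,
    conversion_slope = 0.65,  # baseline LDI -> optimized-variant LDI
    conversion_intercept = 0.33
  )
}

#' Trial timing specification
#'
#' Stimuli are shown for `stim_duration_s` (default 2.0 s) with at least
#' `min_isi_s` (0.5 s) between trials; trials are partially self-paced with a
#' minimum total length of `min_trial_s` (2.5 s).
#' `assumed_response_latency_s` is the response latency (from trial onset)
#' assumed when estimating expected session duration.
#'
#' @param stim_duration_s Stimulus duration in seconds.
#' @param min_isi_s Minimum inter-stimulus interval in seconds.
#' @param min_trial_s Minimum total trial length in seconds.
#' @param assumed_response_latency_s Assumed response latency in seconds.
#' @return A list of class `mst_timing`.
#' @export
timing_spec <- function(stim_duration_s = 2.0, min_isi_s = 0.5,
                        min_trial_s = 2.5, assumed_response_latency_s = 1.5) {
  vals <- c(stim_duration_s, min_isi_s, min_trial_s, assumed_response_latency_s)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop0("timing values must be finite and non-negative")
  }
  if (min_trial_s < stim_duration_s) {
    stop0("`min_trial_s` must be at least `stim_duration_s`")
  }
  structure(list(stim_duration_s = stim_duration_s, min_isi_s = min_isi_s,
                 min_trial_s = min_trial_s,
                 assumed_response_latency_s = assumed_response_latency_s),
            class = "mst_timing")
}

#' Guided-practice block specification
#'
#' The study-test variant uses four practice study trials and six practice
#' test trials (three guided, three unguided); the continuous variant uses a
#' single block of nine practice trials (five guided, four unguided).
#' Guided trials force the correct answer.
#'
#' @param format `"study_test"` or `"continuous"`.
#' @param n_study Practice study trials (study-test only).
#' @param n_guided,n_unguided Guided / unguided practice test trials.
#' @return A list of class `mst_practice`.
#' @export
practice_spec <- function(format = c("study_test", "continuous"),
                          n_study = NULL, n_guided = NULL, n_unguided = NULL) {
  format <- match.arg(format)
  if (format == "study_test") {
    n_study <- n_study %||% 4L
    n_guided <- n_guided %||% 3L
    n_unguided <- n_unguided %||% 3L
  } else {
    n_study <- 0L
    n_guided <- n_guided %||% 5L
    n_unguided <- n_unguided %||% 4L
  }
  counts <- c(n_study, n_guided, n_unguided)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop0("practice counts must be non-negative integers")
  }
  structure(list(format = format, n_study = as.integer(n_study),
                 n_guided = as.integer(n_guided),
                 n_unguided = as.integer(n_unguided)),
            class = "mst_practice")
}

#' Task-variant design specification
#'
#' Describes one realization of the task: format (study-test or continuous),
#' response prompt (three-choice old/similar/new, `"OSN"`, or two-choice
#' old/new, `"ON"`), condition allocations, lag bands (continuous only),
#' optional practice block, timing, and a seed.
#'
#' In the continuous format the first presentations of later repeats and
#' lures double as the novel foils, so `n_foil` is not defined there;
#' `lag_bands` is a data.frame with columns `lo`, `hi`, `n_repeat`, `n_lure`
#' giving, per band of allowed gaps (in trials), how many repeat and lure
#' probes must fall in that band.
#'
#' @param format `"study_test"` or `"continuous"`.
#' @param prompt `"OSN"` or `"ON"`.
#' @param n_repeat,n_lure Test/probe allocations.
#' @param n_foil Novel foils at test (study-test only).
#' @param n_first First presentations (continuous only).
#' @param lag_bands Lag-band table (continuous only); default splits each
#'   condition as evenly as possible across bands 4--11 and 20--99.
#' @param practice An [practice_spec()] or `NULL`.
#' @param timing A [timing_spec()].
#' @param label Optional variant label carried into schedules.
#' @param seed Integer seed used by the schedule builders.
#' @return A list of class `mst_design`.
#' @export
design_spec <- function(format = c("study_test", "continuous"),
                        prompt = c("OSN", "ON"),
                        n_repeat, n_lure, n_foil = NULL, n_first = NULL,
                        lag_bands = NULL, practice = NULL,
                        timing = timing_spec(), label = NULL, seed = NULL) {
  format <- match.arg(format)
  prompt <- match.arg(prompt)
  chk_count <- function(x, what, min = 0L) {
    if (!is.numeric(x) || length(x) != 1L || x < min || x != round(x)) {
      stop0("`", what, "` must be an integer >= ", min)
    }
    as.integer(x)
  }
  n_repeat <- chk_count(n_repeat, "n_repeat")
  n_lure <- chk_count(n_lure, "n_lure")
  if (n_repeat + n_lure < 1L) stop0("need at least one repeat or lure trial")
  if (format == "study_test") {
    n_foil <- chk_count(n_foil, "n_foil")
    if (!is.null(n_first)) stop0("`n_first` applies to the continuous format only")
    if (!is.null(lag_bands)) stop0("`lag_bands` applies to the continuous format only")
    n_study <- n_repeat + n_lure # every tested repeat/lure was studied
  } else {
    if (!is.null(n_foil)) {
      stop0("`n_foil` is not defined for the continuous format: ",
            "first presentations serve as the novel foils")
    }
    n_first <- chk_count(n_first, "n_first", min = 1L)
    if (n_first < n_repeat + n_lure) {
      stop0("`n_first` must be at least n_repeat + n_lure: every probe needs ",
            "an earlier first presentation")
    }
    lag_bands <- lag_bands %||% default_lag_bands(n_repeat, n_lure)
    lag_bands <- as.data.frame(lag_bands)
    need <- c("lo", "hi", "n_repeat", "n_lure")
    if (!all(need %in% names(lag_bands))) {
      stop0("`lag_bands` needs columns lo, hi, n_repeat, n_lure")
    }
    if (any(lag_bands$lo < 1) || any(lag_bands$hi < lag_bands$lo)) {
      stop0("lag bands must satisfy 1 <= lo <= hi")
    }
    if (sum(lag_bands$n_repeat) != n_repeat || sum(lag_bands$n_lure) != n_lure) {
      stop0("lag-band assignments must sum to n_repeat and n_lure")
    }
    n_study <- NULL
  }
  if (!is.null(practice)) {
    if (!inherits(practice, "mst_practice")) stop0("`practice` must come from practice_spec()")
    if (practice$format != format) stop0("practice block format must match the design format")
  }
  if (!inherits(timing, "mst_timing")) stop0("`timing` must come from timing_spec()")
  structure(list(format = format, prompt = prompt,
                 n_study = n_study, n_first = n_first,
                 n_repeat = n_repeat, n_lure = n_lure, n_foil = n_foil,
                 lag_bands = lag_bands, practice = practice, timing = timing,
                 label = label, seed = seed),
            class = "mst_design")
}

# Default lag bands: the canonical short (4-11) and long (20-99) gap bands,
# each condition split as evenly as possible between them (full-length
# continuous: 32/32 per condition; reduced: repeats 10/10, lures 22/22).
default_lag_bands <- function(n_repeat, n_lure) {
  data.frame(
    lo = c(4L, 20L), hi = c(11L, 99L),
    n_repeat = c(ceiling(n_repeat / 2), floor(n_repeat / 2)),
    n_lure = c(ceiling(n_lure / 2), floor(n_lure / 2))
  )
}

#' Canonical task-variant designs
#'
#' Shorthand for the four studied variants: the full-length study-test task
#' (128 study items; 64 repeats / 64 lures / 64 foils at test; 320 trials),
#' the full-length continuous task (128 firsts / 64 repeats / 64 lures;
#' 256 trials; 32 short-gap and 32 long-gap probes per condition), and the
#' reduced variants that protect lure trials (study-test 20/44/20, 148
#' trials; continuous 64 firsts / 20 repeats / 44 lures, 128 trials).
#'
#' @param variant One of `"full-st"`, `"full-cont"`, `"reduced-st"`,
#'   `"reduced-cont"`.
#' @param prompt `"OSN"` or `"ON"`.
#' @param practice Logical: include the guided practice block?
#' @param timing A [timing_spec()].
#' @param seed Integer seed.
#' @return An [design_spec()] object.
#' @export
#' @examples
#' spec <- mst_variant_spec("reduced-cont", seed = 7)
mst_variant_spec <- function(variant = c("full-st", "full-cont",
                                         "reduced-st", "reduced-cont"),
                             prompt = c("OSN", "ON"), practice = FALSE,
                             timing = timing_spec(), seed = NULL) {
  variant <- match.arg(variant)
  prompt <- match.arg(prompt)
  fmt <- if (grepl("cont", variant)) "continuous" else "study_test"
  pr <- if (practice) practice_spec(fmt) else NULL
  spec <- switch(variant,
    "full-st" = design_spec("study_test", prompt, n_repeat = 64L,
                            n_lure = 64L, n_foil = 64L, practice = pr,
                            timing = timing, label = variant, seed = seed),
    "reduced-st" = design_spec("study_test", prompt, n_repeat = 20L,
                               n_lure = 44L, n_foil = 20L, practice = pr,
                               timing = timing, label = variant, seed = seed),
    "full-cont" = design_spec("continuous", prompt, n_first = 128L,
                              n_repeat = 64L, n_lure = 64L, practice = pr,
                              timing = timing, label = variant, seed = seed),
    "reduced-cont" = design_spec("continuous", prompt, n_first = 64L,
                                 n_repeat = 20L, n_lure = 44L, practice = pr,
                                 timing = timing, label = variant, seed = seed)
  )
  spec
}

#' @export
print.mst_design <- function(x, ...) {
  cat("MST design:", x$label %||% x$format, "/", x$prompt, "\n")
  if (x$format == "study_test") {
    cat("  study", x$n_study, "| test", x$n_repeat, "repeat /", x$n_lure,
        "lure /", x$n_foil, "foil\n")
  } else {
    cat("  firsts", x$n_first, "| probes", x$n_repeat, "repeat /", x$n_lure,
        "lure\n")
    print(x$lag_bands)
  }
  invisible(x)
}
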