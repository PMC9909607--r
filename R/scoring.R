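# Scoring: response logs -> outcome measures.
#
# Outcome measures:
#   LDI    = p("similar" | lure)  - p("similar" | foil)   (OSN prompt)
#   REC    = p("old" | repeat)    - p("old" | foil)       (corrected recognition)
#   d'(TL) = z(p(old|repeat)) - z(p(old|lure))   target vs. lure discriminability
#   d'(TF) = z(p(old|repeat)) - z(p(old|foil))   target vs. foil discriminability
# In the continuous format the first presentations are the novel foils, so
# condition "first" is mapped to "foil" at tabulation.

RESPONSES <- c("old", "similar", "new", "none")

allowed_responses <- function(prompt) {
  if (prompt == "OSN") c("old", "similar", "new", "none") else c("old", "new", "none")
}

#' Construct / validate a response log
#'
#' A response log is the schedule's trial table joined with per-trial
#' `response` (`old` / `similar` / `new`, or `none` for an omission) and
#' optional `rt_ms`, plus session metadata carried as attributes.  The OSN
#' (three-choice) prompt permits all three responses; the ON (two-choice)
#' prompt permits only `old` / `new`.
#'
#' @param trials Data.frame with the schedule columns plus `response` and
#'   optionally `rt_ms`.
#' @param participant Participant identifier.
#' @param variant Variant label.
#' @param prompt `"OSN"` or `"ON"`.
#' @return The validated data.frame, class `mst_response_log`, with
#'   attributes `participant`, `variant`, `prompt`.
#' @export
response_log <- function(trials, participant = NA, variant = NA,
                         prompt = c("OSN", "ON")) {
  prompt <- match.arg(prompt)
  trials <- as.data.frame(trials)
  need <- c("trial_index", "phase", "condition", "set_id", "pair_id",
            "exemplar", "lure_bin", "lag", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop0("response log is missing columns: ",
                          paste(miss, collapse = ", "))
  if (!"rt_ms" %in% names(trials)) trials$rt_ms <- NA_real_
  bad <- which(!trials$response %in% allowed_responses(prompt))
  if (length(bad)) {
    stop0("row ", bad[1L], ": response '", trials$response[bad[1L]],
          "' not allowed under the ", prompt, " prompt")
  }
  structure(trials, class = c("mst_response_log", "data.frame"),
            participant = participant, variant = variant, prompt = prompt)
}

log_prompt <- function(log) {
  attr(log, "prompt") %||% if (any(log$response == "similar")) "OSN" else "ON"
}

# Scored trials with continuous firsts mapped to foils.
scored_trials <- function(log) {
  sc <- log[log$phase %in% c("test", "continuous"), , drop = FALSE]
  sc$condition[sc$condition == "first"] <- "foil"
  sc
}

#' Tabulate a response log
#'
#' Counts responses per condition over the scored block and converts them
#' to rates.  Under the default omission policy (`"exclude"`) rates are
#' computed over emitted responses and omissions are tallied separately;
#' under `"count_as_new"` omissions are scored as `new` responses.
#'
#' @param log A response log.
#' @param omission `"exclude"` or `"count_as_new"`.
#' @return A list of class `mst_rate_table`: `counts` and `rates`
#'   (condition x response matrices), `n_scored`, `n_omitted`, `prompt`.
#' @export
tabulate_responses <- function(log, omission = c("exclude", "count_as_new")) {
  omission <- match.arg(omission)
  prompt <- log_prompt(log)
  sc <- scored_trials(log)
  conds <- c("repeat", "lure", "foil")
  counts <- t(vapply(conds, function(co) {
    r <- sc$response[sc$condition == co]
    vapply(RESPONSES, function(x) sum(r == x), integer(1))
  }, integer(4)))
  dimnames(counts) <- list(condition = conds, response = RESPONSES)
  n_omitted <- counts[, "none"]
  if (omission == "count_as_new") {
    counts[, "new"] <- counts[, "new"] + counts[, "none"]
    counts[, "none"] <- 0L
  }
  emitted <- counts[, c("old", "similar", "new"), drop = FALSE]
  n_scored <- rowSums(emitted)
  rates <- sweep(emitted, 1, pmax(n_scored, 1L), "/")
  rates[n_scored == 0L, ] <- NA_real_
  structure(list(counts = counts, rates = rates, n_scored = n_scored,
                 n_omitted = n_omitted, prompt = prompt,
                 omission = omission),
            class = "mst_rate_table")
}

#' @export
print.mst_rate_table <- function(x, ...) {
  cat("MST rate table (", x$prompt, " prompt, omissions ", x$omission, ")\n",
      sep = "")
  print(x$counts)
  print(round(x$rates, 3))
  invisible(x)
}

rate_of <- function(tab, cond, resp, what) {
  if (tab$n_scored[cond] < 1L) {
    stop0("no scored ", cond, " trials: cannot compute ", what)
  }
  tab$rates[cond, resp]
}

#' Lure discrimination index
#'
#' `p("similar" | lure) - p("similar" | foil)`; the subtraction corrects
#' for bias in the use of the "similar" response.  Defined only for the
#' three-choice (OSN) prompt.
#'
#' @param tab An [tabulate_responses()] table (a response log is also
#'   accepted and tabulated on the fly).
#' @return LDI in `[-1, 1]`.
#' @export
ldi <- function(tab) {
  if (inherits(tab, "mst_response_log")) tab <- tabulate_responses(tab)
  if (tab$prompt != "OSN") {
    stop0("LDI requires the OSN prompt (no 'similar' response under ON)")
  }
  rate_of(tab, "lure", "similar", "LDI") -
    rate_of(tab, "foil", "similar", "LDI")
}

#' Corrected recognition
#'
#' `p("old" | repeat) - p("old" | foil)`: traditional recognition corrected
#' for the base rate of "old" responses.
#'
#' @inheritParams ldi
#' @return REC in `[-1, 1]`.
#' @export
rec <- function(tab) {
  if (inherits(tab, "mst_response_log")) tab <- tabulate_responses(tab)
  rate_of(tab, "repeat", "old", "REC") - rate_of(tab, "foil", "old", "REC")
}

#' Signal-detection d-prime
#'
#' `qnorm(hit) - qnorm(fa)` with the standard extreme-rate adjustment:
#' a rate of 0 is replaced by `1/(2N)` and a rate of 1 by `1 - 1/(2N)`,
#' where `N` is the relevant trial count (required only when an adjustment
#' is actually needed).
#'
#' @param hit_rate,fa_rate Hit and false-alarm rates in `[0, 1]`.
#' @param n_signal,n_noise Trial counts behind each rate.
#' @return The discriminability estimate.
#' @export
#' @examples
#' dprime(0.8, 0.2)              # 2 * qnorm(0.8)
#' dprime(1, 0.5, n_signal = 20) # uses 1 - 1/40 as the hit rate
dprime <- function(hit_rate, fa_rate, n_signal = NULL, n_noise = NULL) {
  adj <- function(p, n, what) {
    if (is.na(p)) return(NA_real_)
    if (p < 0 || p > 1) stop0(what, " rate must be in [0, 1]")
    if (p == 0 || p == 1) {
      if (is.null(n) || n < 1) {
        stop0("extreme ", what, " rate needs its trial count for adjustment")
      }
      p <- if (p == 0) 1 / (2 * n) else 1 - 1 / (2 * n)
    }
    p
  }
  stats::qnorm(adj(hit_rate, n_signal, "hit")) -
    stats::qnorm(adj(fa_rate, n_noise, "false-alarm"))
}

#' Target/lure and target/foil d-prime from a rate table
#'
#' `dprime_tl()` measures discrimination of true repetitions from similar
#' lures (hits = "old" to repeats, false alarms = "old" to lures);
#' `dprime_tf()` measures discrimination of repetitions from novel foils
#' ("old" to foils as the false-alarm rate).  For OSN logs the "old" rates
#' already ignore the similar/new split, which is exactly the two-choice
#' collapse ("similar" counted as "new").
#'
#' @inheritParams ldi
#' @return A d-prime estimate.
#' @export
dprime_tl <- function(tab) {
  if (inherits(tab, "mst_response_log")) tab <- tabulate_responses(tab)
  dprime(rate_of(tab, "repeat", "old", "d'(TL)"),
         rate_of(tab, "lure", "old", "d'(TL)"),
         tab$n_scored["repeat"], tab$n_scored["lure"])
}

#' @rdname dprime_tl
#' @export
dprime_tf <- function(tab) {
  if (inherits(tab, "mst_response_log")) tab <- tabulate_responses(tab)
  dprime(rate_of(tab, "repeat", "old", "d'(TF)"),
         rate_of(tab, "foil", "old", "d'(TF)"),
         tab$n_scored["repeat"], tab$n_scored["foil"])
}

#' Session validity decision
#'
#' Sessions from unengaged participants are filtered on the traditional
#' recognition measure: OSN sessions need `REC >= rec_min` (default 0.5),
#' ON sessions need `d'(TF) >= dtf_min` (default 1.5).  Thresholds are
#' inclusive.
#'
#' @param report An `mst_score_report` (from [score_session()]).
#' @param prompt `"OSN"` or `"ON"`; defaults to the report's prompt.
#' @param rec_min,dtf_min Validity thresholds.
#' @return A list: `valid` (logical) and `reason` (character).
#' @export
validity_filter <- function(report, prompt = NULL,
                            rec_min = mst_defaults()$rec_min,
                            dtf_min = mst_defaults()$dtf_min) {
  prompt <- prompt %||% report$prompt
  if (prompt == "OSN") {
    ok <- !is.na(report$rec) && report$rec >= rec_min
    list(valid = ok,
         reason = if (ok) "REC at or above threshold"
                  else sprintf("REC %.3f below threshold %.2f",
                               report$rec, rec_min))
  } else {
    ok <- !is.na(report$dprime_tf) && report$dprime_tf >= dtf_min
    list(valid = ok,
         reason = if (ok) "d'(TF) at or above threshold"
                  else sprintf("d'(TF) %.3f below threshold %.2f",
                               report$dprime_tf, dtf_min))
  }
}

#' Per-bin lure response curves
#'
#' Rates of "old" (and, under OSN, "similar") responses to lures, split by
#' lure-difficulty bin (bin 1 = most similar lure).  Monotonicity over bins
#' is an empirical property of the data, not enforced here.
#'
#' @param log A response log.
#' @param omission Omission policy, as in [tabulate_responses()].
#' @return A data.frame: `lure_bin`, `n`, `old_rate`, `similar_rate`
#'   (`NA` under ON).
#' @export
bin_curve <- function(log, omission = c("exclude", "count_as_new")) {
  omission <- match.arg(omission)
  prompt <- log_prompt(log)
  sc <- scored_trials(log)
  lures <- sc[sc$condition == "lure", , drop = FALSE]
  if (omission == "count_as_new") {
    lures$response[lures$response == "none"] <- "new"
  } else {
    lures <- lures[lures$response != "none", , drop = FALSE]
  }
  out <- data.frame(lure_bin = 1:5, n = 0L, old_rate = NA_real_,
                    similar_rate = NA_real_)
  for (b in 1:5) {
    r <- lures$response[lures$lure_bin == b]
    out$n[b] <- length(r)
    if (length(r)) {
      out$old_rate[b] <- mean(r == "old")
      out$similar_rate[b] <- if (prompt == "OSN") mean(r == "similar") else NA_real_
    }
  }
  out
}

#' Score one session
#'
#' Computes every outcome measure applicable to the session's prompt (LDI
#' and REC for OSN; the d-prime measures for both prompts, using the
#' two-choice collapse for OSN logs), the per-bin lure curves, the validity
#' decision, and -- for OSN sessions -- a review flag for extreme over- or
#' under-use of the "similar" response (overall p("similar") outside
#' `similar_use_range`; the session is flagged, never dropped).
#'
#' @param log A response log.
#' @param omission Omission policy.
#' @param rec_min,dtf_min Validity thresholds.
#' @param similar_use_range Review-flag bounds on overall p("similar").
#' @return A list of class `mst_score_report`.
#' @export
score_session <- function(log, omission = c("exclude", "count_as_new"),
                          rec_min = mst_defaults()$rec_min,
                          dtf_min = mst_defaults()$dtf_min,
                          similar_use_range = mst_defaults()$similar_use_range) {
  omission <- match.arg(omission)
  tab <- tabulate_responses(log, omission)
  prompt <- tab$prompt
  is_osn <- prompt == "OSN"
  report <- list(
    participant = attr(log, "participant"),
    variant = attr(log, "variant"),
    prompt = prompt,
    ldi = if (is_osn) ldi(tab) else NA_real_,
    rec = rec(tab),
    dprime_tl = dprime_tl(tab),
    dprime_tf = dprime_tf(tab),
    bin_curve = bin_curve(log, omission),
    counts = tab$counts,
    n_scored = tab$n_scored,
    n_omitted = tab$n_omitted
  )
  if (is_osn) {
    sc <- scored_trials(log)
    emitted <- sc$response[sc$response != "none"]
    p_sim <- if (length(emitted)) mean(emitted == "similar") else NA_real_
    report$p_similar_overall <- p_sim
    report$flag_similar_use <- !is.na(p_sim) &&
      (p_sim < similar_use_range[1] || p_sim > similar_use_range[2])
  } else {
    report$p_similar_overall <- NA_real_
    report$flag_similar_use <- FALSE
  }
  v <- validity_filter(report, prompt, rec_min, dtf_min)
  report$valid <- v$valid
  report$valid_reason <- v$reason
  class(report) <- "mst_score_report"
  report
}

#' @export
print.mst_score_report <- function(x, ...) {
  cat("MST score report (", x$prompt, ")\n", sep = "")
  cat(sprintf("  LDI %.3f | REC %.3f | d'(TL) %.3f | d'(TF) %.3f\n",
              x$ldi, x$rec, x$dprime_tl, x$dprime_tf))
  cat("  valid:", x$valid, "-", x$valid_reason, "\n")
  invisible(x)
}

#' Long-format multi-session score export
#'
#' Flattens a collection of score reports into the tidy long table
#' (`participant`, `session`, `variant`, `metric`, `value`) consumed by
#' downstream mixed-model analyses.
#'
#' @param reports A list of `mst_score_report`s.
#' @param sessions Optional session indices (defaults to position).
#' @return A long data.frame.
#' @export
scores_long <- function(reports, sessions = seq_along(reports)) {
  rows <- lapply(seq_along(reports), function(i) {
    rp <- reports[[i]]
    metrics <- c(ldi = rp$ldi, rec = rp$rec, dprime_tl = rp$dprime_tl,
                 dprime_tf = rp$dprime_tf)
    data.frame(participant = rp$participant %||% NA,
               session = sessions[i],
               variant = rp$variant %||% NA,
               metric = names(metrics), value = unname(metrics))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
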