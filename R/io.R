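# File formats: bank CSV, schedule CSV (+ JSON design mirror), response-log
# CSV and jsPsych-style JSON, score-report JSON, paired-scores CSV.
# All CSVs are comma-separated UTF-8 with a required header, no quoting of
# numerics; JSON uses snake_case keys matching the CSV headers exactly.

read_text_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  if (!nrow(df)) stop0(path, ": no data rows")
  df
}

# Strict integer parsing with line-numbered errors (line 1 is the header).
parse_int_col <- function(vals, name, allow_na = FALSE) {
  out <- suppressWarnings(as.integer(vals))
  bad <- which(is.na(out) & !(allow_na & (is.na(vals) | vals == "")))
  if (length(bad)) {
    stop0("line ", bad[1L] + 1L, ": column '", name,
          "' has non-integer value '", vals[bad[1L]], "'")
  }
  out
}

parse_num_col <- function(vals, name, allow_na = TRUE) {
  out <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(out) & !(allow_na & (is.na(vals) | vals == "")))
  if (length(bad)) {
    stop0("line ", bad[1L] + 1L, ": column '", name,
          "' has non-numeric value '", vals[bad[1L]], "'")
  }
  out
}

need_cols <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop0(what, " is missing columns: ", paste(miss, collapse = ", "))
  }
}

write_plain_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read / write a stimulus-bank CSV
#'
#' Header `set_id,pair_id,lure_bin`; strict integer parsing with
#' line-numbered errors.
#'
#' @param path File path.
#' @param bank A bank data.frame (for writing).
#' @return `read_bank()` returns an `mst_bank`; `write_bank()` returns the
#'   path, invisibly.
#' @export
read_bank <- function(path) {
  df <- read_text_csv(path)
  need_cols(df, c("set_id", "pair_id", "lure_bin"), "bank file")
  bank <- data.frame(set_id = parse_int_col(df$set_id, "set_id"),
                     pair_id = parse_int_col(df$pair_id, "pair_id"),
                     lure_bin = parse_int_col(df$lure_bin, "lure_bin"))
  class(bank) <- c("mst_bank", "data.frame")
  validate_bank(bank)
  bank
}

#' @rdname read_bank
#' @export
write_bank <- function(bank, path) {
  validate_bank(bank)
  write_plain_csv(as.data.frame(bank)[c("set_id", "pair_id", "lure_bin")], path)
  invisible(path)
}

schedule_csv_cols <- c("trial_index", "phase", "condition", "set_id",
                       "pair_id", "exemplar", "lure_bin", "lag", "guided")

#' Read / write a trial-schedule CSV (with optional JSON design mirror)
#'
#' The CSV has header `trial_index,phase,condition,set_id,pair_id,exemplar,`
#' `lure_bin,lag,guided`, `lag` left empty when undefined.  The JSON mirror
#' carries the full design specification for provenance; when reading
#' without it, a design is inferred from the trial list (counts and format;
#' lag bands are then unknown and band checks are skipped by
#' [validate_schedule()]).
#'
#' @param schedule An `mst_schedule` (for writing).
#' @param path CSV path.
#' @param json_path Optional design JSON path.
#' @return `read_schedule()` returns an `mst_schedule`; `write_schedule()`
#'   the CSV path, invisibly.
#' @export
write_schedule <- function(schedule, path, json_path = NULL) {
  tr <- schedule$trials[schedule_csv_cols]
  write_plain_csv(tr, path)
  if (!is.null(json_path)) {
    d <- schedule$design
    payload <- list(
      design = list(
        format = d$format, prompt = d$prompt, n_study = d$n_study,
        n_first = d$n_first, n_repeat = d$n_repeat, n_lure = d$n_lure,
        n_foil = d$n_foil, lag_bands = d$lag_bands,
        practice = if (!is.null(d$practice)) unclass(d$practice),
        timing = unclass(d$timing), label = d$label, seed = d$seed),
      metadata = schedule$metadata)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, json_path = NULL) {
  df <- read_text_csv(path)
  need_cols(df, schedule_csv_cols, "schedule file")
  ok_guided <- df$guided %in% c("TRUE", "FALSE")
  if (!all(ok_guided)) {
    stop0("line ", which(!ok_guided)[1L] + 1L,
          ": column 'guided' must be TRUE or FALSE")
  }
  tr <- data.frame(
    trial_index = parse_int_col(df$trial_index, "trial_index"),
    phase = df$phase, condition = df$condition,
    set_id = parse_int_col(df$set_id, "set_id"),
    pair_id = parse_int_col(df$pair_id, "pair_id"),
    exemplar = df$exemplar,
    lure_bin = parse_int_col(df$lure_bin, "lure_bin"),
    lag = parse_int_col(df$lag, "lag", allow_na = TRUE),
    guided = df$guided == "TRUE")
  design <- if (!is.null(json_path)) {
    j <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    d <- j$design
    design_spec(d$format, d$prompt, n_repeat = d$n_repeat, n_lure = d$n_lure,
                n_foil = d$n_foil, n_first = d$n_first,
                lag_bands = d$lag_bands,
                practice = if (!is.null(d$practice)) {
                  practice_spec(d$practice$format, d$practice$n_study,
                                d$practice$n_guided, d$practice$n_unguided)
                },
                timing = do.call(timing_spec, as.list(d$timing)),
                label = d$label, seed = d$seed)
  } else {
    infer_design(tr)
  }
  structure(list(design = design, trials = tr,
                 metadata = list(variant = design$label %||% design$format,
                                 sets_used = sort(unique(tr$set_id)))),
            class = "mst_schedule")
}

# Reconstruct a design from a raw trial list (no lag-band information).
infer_design <- function(tr) {
  scored <- tr[!startsWith(tr$phase, "practice"), , drop = FALSE]
  prompt <- "OSN" # prompt is not encoded in a schedule file
  if (any(scored$phase == "continuous")) {
    d <- design_spec("continuous", prompt,
                     n_first = sum(scored$condition == "first"),
                     n_repeat = sum(scored$condition == "repeat"),
                     n_lure = sum(scored$condition == "lure"))
    d$lag_bands <- NULL
    d
  } else {
    design_spec("study_test", prompt,
                n_repeat = sum(scored$condition == "repeat"),
                n_lure = sum(scored$condition == "lure"),
                n_foil = sum(scored$condition == "foil"))
  }
}

log_csv_cols <- c(schedule_csv_cols[schedule_csv_cols != "guided"],
                  "response", "rt_ms")

#' Read / write a response log
#'
#' CSV header `trial_index,phase,condition,set_id,pair_id,exemplar,`
#' `lure_bin,lag,response,rt_ms`.  `read_response_log()` also accepts a
#' jsPsych-style JSON dialect: a flat array of per-trial objects using the
#' same snake_case keys, optionally carrying constant `participant`,
#' `variant`, and `prompt` fields on each trial object (unknown extra keys
#' are ignored).  JSON input is detected by a `.json` extension or a
#' leading `[`.  When `prompt` is not supplied anywhere it is inferred from
#' the response vocabulary ("similar" present implies OSN).
#'
#' @param path File path.
#' @param participant,variant,prompt Session metadata (override anything in
#'   the file).
#' @param log An `mst_response_log` (for writing).
#' @param format `"csv"` or `"json"` (jsPsych-style mirror).
#' @return `read_response_log()` returns an `mst_response_log`;
#'   `write_response_log()` the path, invisibly.
#' @export
read_response_log <- function(path, participant = NULL, variant = NULL,
                              prompt = NULL) {
  first_char <- substr(trimws(readChar(path, 200L)), 1L, 1L)
  if (grepl("\\.json$", path, ignore.case = TRUE) || first_char == "[") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    raw <- as.data.frame(raw)
    need_cols(raw, log_csv_cols[log_csv_cols != "rt_ms"], "jsPsych-style log")
    participant <- participant %||% raw$participant[1L]
    variant <- variant %||% raw$variant[1L]
    prompt <- prompt %||% raw$prompt[1L]
    df <- raw[intersect(log_csv_cols, names(raw))]
    if (!"rt_ms" %in% names(df)) df$rt_ms <- NA_real_
    df$guided <- if ("guided" %in% names(raw)) isTRUE_vec(raw$guided) else FALSE
    df$lag <- suppressWarnings(as.integer(df$lag))
  } else {
    chr <- read_text_csv(path)
    need_cols(chr, log_csv_cols, "response-log file")
    df <- data.frame(
      trial_index = parse_int_col(chr$trial_index, "trial_index"),
      phase = chr$phase, condition = chr$condition,
      set_id = parse_int_col(chr$set_id, "set_id"),
      pair_id = parse_int_col(chr$pair_id, "pair_id"),
      exemplar = chr$exemplar,
      lure_bin = parse_int_col(chr$lure_bin, "lure_bin"),
      lag = parse_int_col(chr$lag, "lag", allow_na = TRUE),
      guided = if ("guided" %in% names(chr)) chr$guided == "TRUE" else FALSE,
      response = chr$response,
      rt_ms = parse_num_col(chr$rt_ms, "rt_ms", allow_na = TRUE))
  }
  prompt <- prompt %||% (if (any(df$response == "similar")) "OSN" else "ON")
  response_log(df, participant = participant %||% NA,
               variant = variant %||% NA, prompt = prompt)
}

isTRUE_vec <- function(x) !is.na(x) & (x == TRUE | x == "TRUE")

#' @rdname read_response_log
#' @export
write_response_log <- function(log, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(log)[log_csv_cols]
  if (format == "csv") {
    write_plain_csv(df, path)
  } else {
    df$participant <- attr(log, "participant")
    df$variant <- attr(log, "variant")
    df$prompt <- attr(log, "prompt")
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = FALSE)
  }
  invisible(path)
}

#' Write a score report as JSON
#'
#' All score-report fields plus the raw counts matrix, snake_case keys.
#'
#' @param report An `mst_score_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_score_report <- function(report, path) {
  payload <- list(
    participant = report$participant, variant = report$variant,
    prompt = report$prompt,
    ldi = report$ldi, rec = report$rec,
    dprime_tl = report$dprime_tl, dprime_tf = report$dprime_tf,
    valid = report$valid, valid_reason = report$valid_reason,
    flag_similar_use = report$flag_similar_use,
    p_similar_overall = report$p_similar_overall,
    bin_curve = report$bin_curve,
    counts = as.data.frame.matrix(report$counts),
    n_scored = as.list(report$n_scored),
    n_omitted = as.list(report$n_omitted))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read / write a paired-scores CSV
#'
#' Header `participant,baseline,variant`: one row per participant with the
#' baseline score and the alternate-variant score.
#'
#' @param path File path.
#' @param scores Data.frame with columns `participant`, `baseline`,
#'   `variant` (for writing).
#' @return `read_paired_scores()` returns the data.frame;
#'   `write_paired_scores()` the path, invisibly.
#' @export
read_paired_scores <- function(path) {
  df <- read_text_csv(path)
  need_cols(df, c("participant", "baseline", "variant"), "paired-scores file")
  data.frame(participant = df$participant,
             baseline = parse_num_col(df$baseline, "baseline", allow_na = FALSE),
             variant = parse_num_col(df$variant, "variant", allow_na = FALSE))
}

#' @rdname read_paired_scores
#' @export
write_paired_scores <- function(scores, path) {
  need_cols(scores, c("participant", "baseline", "variant"), "paired scores")
  write_plain_csv(scores[c("participant", "baseline", "variant")], path)
  invisible(path)
}
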