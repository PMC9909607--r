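# Shared fixtures, built in code.

# One canonical synthetic bank per test run (6 sets x 192 pairs).
canonical_bank <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- make_synthetic_bank(seed = 101)
    b
  }
})

bank_set <- function(s = 1L) {
  b <- canonical_bank()
  b[b$set_id == s, ]
}

# Build a response log with exact per-condition response counts, e.g.
# log_from_counts(list("lure" = c(similar = 22, old = 10, new = 12), ...)).
log_from_counts <- function(counts, prompt = "OSN", phase = "test") {
  cond <- rep(names(counts), vapply(counts, sum, numeric(1)))
  resp <- unlist(lapply(counts, function(cc) rep(names(cc), cc)),
                 use.names = FALSE)
  n <- length(cond)
  df <- data.frame(trial_index = seq_len(n), phase = phase,
                   condition = cond, set_id = 1L, pair_id = seq_len(n),
                   exemplar = "a", lure_bin = rep_len(1:5, n),
                   lag = NA_integer_, response = resp, rt_ms = NA_real_)
  response_log(df, prompt = prompt)
}

# Per-participant (session 1, session 2) LDI pairs for a simulated cohort.
cohort_ldi_pairs <- function(schedule, cohort, n, seed) {
  sim <- simulate_cohort(schedule, cohort, n, 2L, seed = seed)
  t(vapply(sim$logs,
           function(l) c(score_session(l[[1]])$ldi, score_session(l[[2]])$ldi),
           numeric(2)))
}
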