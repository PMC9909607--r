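# Duration accounting for the task variants.
#
# Reference median component durations (seconds) measured for web-delivered
# administrations of the baseline full-length study-test task, the reduced
# study-test task with a guided practice block, and the reduced continuous
# task.  The baseline was measured in two independent experiments
# (replicates "a" and "b"); replicates are averaged before summing.

#' Reference median phase durations
#'
#' Bundled reference timings used for duration accounting: median
#' instruction and task-phase durations, in seconds, for the baseline
#' full-length study-test variant (measured twice), the reduced study-test
#' variant, and the reduced continuous variant.
#'
#' @return A data.frame: `variant`, `component`, `replicate`, `seconds`.
#' @export
mst_reference_durations <- function() {
  data.frame(
    variant = c(rep("baseline", 8L), rep("reduced_study_test", 4L),
                rep("reduced_continuous", 2L)),
    component = c(rep(c("study_instructions", "study_phase",
                        "test_instructions", "test_phase"), each = 2L),
                  "study_instructions", "study_phase",
                  "test_instructions", "test_phase",
                  "instructions", "task_phase"),
    replicate = c(rep(c("a", "b"), 4L), rep("a", 6L)),
    seconds = c(21.3, 24.3, 240.7, 240.1, 95.06, 99.64, 377.5, 370.0,
                25.4, 123.6, 49.5, 167.5,
                64.7, 251.0)
  )
}

#' Summarize variant durations
#'
#' Averages replicate measurements per component, sums components per
#' variant, and reports total minutes plus the reduced-continuous /
#' baseline ratio and the corresponding percent reduction in running time.
#'
#' @param durations A data.frame in the shape of
#'   [mst_reference_durations()] (the default).
#' @return A list: `total_s` and `total_min` (named by variant),
#'   `ratio_vs_baseline` (named), and `percent_reduction` for the reduced
#'   continuous variant.
#' @export
#' @examples
#' s <- summarize_durations()
#' round(s$total_min["baseline"], 2) # 12.24
summarize_durations <- function(durations = mst_reference_durations()) {
  comp <- aggregate(seconds ~ variant + component, durations, mean)
  total_s <- tapply(comp$seconds, comp$variant, sum)
  total_min <- total_s / 60
  ratio <- total_s / total_s[["baseline"]]
  list(total_s = total_s, total_min = total_min,
       ratio_vs_baseline = ratio,
       percent_reduction =
         100 * (1 - ratio[["reduced_continuous"]]))
}
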