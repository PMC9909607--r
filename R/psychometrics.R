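# Psychometric analysis layer: outlier-robust correlation between task
# variants, Fisher r-to-z comparisons, sample-size computation for
# correlations, effect sizes, common-vs-separate regression testing, and
# cross-variant score conversion.

#' Robust linear fit with FDR-controlled outlier flagging
#'
#' Robust regression plus outlier identification in the ROUT style: the
#' line is fit by iteratively reweighted least squares with Lorentzian
#' weights `1 / (1 + (res / scale)^2)`; the robust residual scale is the
#' 68.27th percentile of the absolute residuals with the small-sample
#' correction `sqrt(n / (n - 2))`; each point's standardized residual is
#' then tested against a t distribution and flagged by a
#' false-discovery-rate-controlled sequential test at rate `q`, working
#' from the largest residual down (stopping at the first non-outlier).
#' The reported correlation `r_clean` is the ordinary Pearson correlation
#' of the unflagged points.
#'
#' @param scores A data.frame of paired scores (first column baseline,
#'   second column variant), or given separately via `x` and `y`.
#' @param q Maximum false-discovery rate (default 1\%).
#' @param x,y Optional numeric vectors instead of `scores`.
#' @param max_iter,tol IRLS controls.
#' @return A list of class `mst_robust_fit`: `slope`, `intercept`,
#'   `residual_scale`, `outlier` (logical flags), `n_removed`, `r_clean`,
#'   `r_all`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(40); y <- 0.3 + 0.65 * x + rnorm(40, sd = 0.1)
#' y[40] <- y[40] + 3          # gross outlier
#' fit <- robust_fit_with_outliers(x = x, y = y)
#' which(fit$outlier)          # 40
robust_fit_with_outliers <- function(scores = NULL, q = mst_defaults()$rout_q,
                                     x = NULL, y = NULL,
                                     max_iter = 100L, tol = 1e-10) {
  if (is.null(x) || is.null(y)) {
    scores <- as.data.frame(scores)
    x <- scores[[1L]]
    y <- scores[[2L]]
  }
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) stop0("paired scores must be finite")
  n <- length(x)
  if (n < 5L) stop0("need at least 5 paired scores")
  if (stats::sd(x) == 0) stop0("degenerate x: zero variance")
  if (q <= 0 || q >= 1) stop0("`q` must be in (0, 1)")
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  rsdr <- robust_scale(y - X %*% beta, n)
  for (it in seq_len(max_iter)) {
    res <- drop(y - X %*% beta)
    if (rsdr < 1e-12) break
    w <- 1 / (1 + (res / rsdr)^2)
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    rsdr <- robust_scale(drop(y - X %*% beta_new), n)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  res <- drop(y - X %*% beta)
  outlier <- logical(n)
  # Degenerate fits (most residuals exactly zero) give a zero robust scale;
  # floor it relative to the largest residual so gross outliers off an
  # otherwise exact line are still flagged while float noise is not.
  rsdr_eff <- max(rsdr, 1e-8 * max(abs(res)), .Machine$double.eps)
  tstat <- abs(res) / rsdr_eff
  p <- 2 * stats::pt(tstat, df = n - 2L, lower.tail = FALSE)
  ord <- order(tstat, decreasing = TRUE)
  for (i in seq_len(n)) {
    alpha_i <- q * (n - (i - 1L)) / n
    if (p[ord[i]] < alpha_i) outlier[ord[i]] <- TRUE else break
  }
  keep <- !outlier
  r_clean <- stats::cor(x[keep], y[keep])
  structure(list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
                 residual_scale = rsdr, outlier = outlier,
                 n_removed = sum(outlier), r_clean = r_clean,
                 r_all = stats::cor(x, y), n = n),
            class = "mst_robust_fit")
}

# 68.27th percentile of |residuals| with the n/(n-K) small-sample
# correction (mimicking division by residual degrees of freedom).
robust_scale <- function(res, n, k = 2L) {
  unname(stats::quantile(abs(res), stats::pnorm(1) - stats::pnorm(-1),
                         names = FALSE) * n / (n - k))
}

#' @export
print.mst_robust_fit <- function(x, ...) {
  cat(sprintf("Robust fit: y = %.3f + %.3f x (RSDR %.3f)\n",
              x$intercept, x$slope, x$residual_scale))
  cat(sprintf("  r = %.3f on %d points after removing %d outlier(s) (r_all %.3f)\n",
              x$r_clean, x$n - x$n_removed, x$n_removed, x$r_all))
  invisible(x)
}

#' Fisher r-to-z comparison of two correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.  The default
#' one-tailed p-value tests the alternative that the first correlation is
#' *smaller* than the second (the direction of interest when asking whether
#' a task variant correlates less with baseline than the reference does):
#' `p = pnorm(z)`.  Two-tailed: `p = 2 * pnorm(-|z|)`.
#'
#' @param r1,n1 First (variant) correlation and its sample size.
#' @param r2,n2 Second (reference) correlation and its sample size.
#' @param tail `"one"` or `"two"`.
#' @return A list: `z`, `p`, `tail`.
#' @export
fisher_compare <- function(r1, n1, r2, n2, tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (n1 < 4 || n2 < 4) stop0("need n >= 4 in both groups")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop0("correlations must lie in (-1, 1)")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- if (tail == "one") stats::pnorm(z) else 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, tail = tail)
}

#' Sample size to resolve a correlation
#'
#' Normal-theory sample size for detecting a correlation `r` at two-sided
#' level `alpha` with the given power:
#' `n = ceiling(((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3)`.
#'
#' @param r Correlation to resolve.
#' @param alpha Two-sided type-I rate.
#' @param power Desired power (`1 - beta`).
#' @return Required sample size (integer).
#' @export
#' @examples
#' sample_size_for_r(0.48, 0.05, 0.8) # 32
sample_size_for_r <- function(r, alpha = 0.05, power = 0.8) {
  if (abs(r) <= 0 || abs(r) >= 1) stop0("`r` must lie in (0, 1) in magnitude")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop0("`alpha` and `power` must lie in (0, 1)")
  }
  z <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(abs(r))
  as.integer(ceiling(z^2 + 3))
}

#' Cohen's d effect size
#'
#' Independent groups: mean difference over the pooled SD.  Paired
#' (`paired = TRUE`): mean change over the SD of the change scores.
#'
#' @param group_a,group_b Numeric score vectors.
#' @param paired Within-subject design?
#' @return The effect size.
#' @export
cohens_d <- function(group_a, group_b, paired = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (paired) {
    if (length(group_a) != length(group_b)) {
      stop0("paired groups must have equal length")
    }
    diffs <- group_a - group_b
    return(mean(diffs) / stats::sd(diffs))
  }
  na <- length(group_a)
  nb <- length(group_b)
  sp <- sqrt(((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
               (na + nb - 2))
  (mean(group_a) - mean(group_b)) / sp
}

#' Extra-sum-of-squares test: common vs. separate regressions
#'
#' Tests whether two groups of paired scores are better fit by separate
#' linear regressions or by a single common one:
#' `F = ((SSE_common - SSE_separate) / 2) / (SSE_separate / (n1 + n2 - 4))`
#' on `(2, n1 + n2 - 4)` degrees of freedom.  The pooled slope, intercept,
#' and Pearson r are reported for use when the common model is retained.
#'
#' @param scores_group1,scores_group2 Data.frames of paired scores
#'   (columns: baseline, variant).
#' @return A list: `F`, `df1`, `df2`, `p`, `pooled_slope`,
#'   `pooled_intercept`, `pooled_r`, `sse_common`, `sse_separate`.
#' @export
common_vs_separate_fit <- function(scores_group1, scores_group2) {
  g1 <- as.data.frame(scores_group1)
  g2 <- as.data.frame(scores_group2)
  sse <- function(x, y) sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
  x1 <- g1[[1L]]; y1 <- g1[[2L]]
  x2 <- g2[[1L]]; y2 <- g2[[2L]]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 3 || n2 < 3) stop0("need at least 3 points per group")
  xp <- c(x1, x2); yp <- c(y1, y2)
  fit_c <- stats::lm.fit(cbind(1, xp), yp)
  sse_c <- sum(fit_c$residuals^2)
  sse_s <- sse(x1, y1) + sse(x2, y2)
  df2 <- n1 + n2 - 4L
  Fst <- ((sse_c - sse_s) / 2) / (sse_s / df2)
  list(F = Fst, df1 = 2L, df2 = df2,
       p = stats::pf(Fst, 2, df2, lower.tail = FALSE),
       pooled_slope = unname(fit_c$coefficients[2L]),
       pooled_intercept = unname(fit_c$coefficients[1L]),
       pooled_r = stats::cor(xp, yp),
       sse_common = sse_c, sse_separate = sse_s)
}

#' Convert scores between the baseline and optimized task variants
#'
#' Applies the cross-variant conversion line `variant = intercept + slope *
#' baseline` (shipped defaults: intercept 0.33, slope 0.65, from the
#' pooled young + older common regression) or its algebraic inverse.
#'
#' @param x Score(s) to convert.
#' @param direction `"baseline_to_omst"` or `"omst_to_baseline"`.
#' @param slope,intercept Conversion line; defaults from [mst_defaults()].
#' @return Converted score(s).
#' @export
#' @examples
#' convert_scores(0)                          # 0.33
#' convert_scores(convert_scores(0.4), "omst_to_baseline") # 0.4
convert_scores <- function(x, direction = c("baseline_to_omst",
                                            "omst_to_baseline"),
                           slope = mst_defaults()$conversion_slope,
                           intercept = mst_defaults()$conversion_intercept) {
  direction <- match.arg(direction)
  if (slope == 0) stop0("conversion slope must be non-zero")
  if (direction == "baseline_to_omst") intercept + slope * x
  else (x - intercept) / slope
}
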