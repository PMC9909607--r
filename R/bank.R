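# Stimulus-bank modelling: sets, pairs, and lure-difficulty bins.
#
# A stimulus bank is a data.frame with one row per target/lure image pair:
#   set_id   -- which independent stimulus set the pair belongs to
#   pair_id  -- identifier within the set
#   lure_bin -- difficulty stratum 1..5; bin 1 is the MOST similar (hardest)
#               lure, i.e. the bin with the highest normative false-alarm
#               rate, and bin 5 the least similar.  This polarity is used
#               consistently throughout the package (the simulator's
#               bin_similarity vector is indexed the same way).
# No image files are involved: the bank models the metadata the task needs.

#' Construct a synthetic stimulus bank
#'
#' Emulates the structure of the task's stimulus material: a number of
#' independent sets, each holding a fixed number of target/lure image pairs,
#' every pair carrying a lure-difficulty bin in 1..5 (bin 1 = most similar
#' lure).  Bins are drawn i.i.d. from `bin_weights`; the canonical bank has
#' six sets of 192 pairs with uniform weights (real stimulus sets are not
#' uniform, but no normative distribution is available, so uniform is the
#' documented default).
#'
#' @param n_sets Number of sets (default 6).
#' @param pairs_per_set Pairs per set (default 192).
#' @param bin_weights Probability vector of length 5 over bins; must sum to 1.
#' @param seed Integer seed; the bank is deterministic given the seed.
#' @return A data.frame of class `mst_bank` with columns
#'   `set_id`, `pair_id`, `lure_bin`.
#' @export
#' @examples
#' bank <- make_synthetic_bank(seed = 1)
#' nrow(bank)          # 1152 pairs
#' bin_counts(bank)
make_synthetic_bank <- function(n_sets = 6L, pairs_per_set = 192L,
                                bin_weights = rep(1 / 5, 5), seed = NULL) {
  if (!is.numeric(n_sets) || length(n_sets) != 1L || n_sets < 1 ||
      n_sets != round(n_sets)) {
    stop0("`n_sets` must be a positive integer")
  }
  if (!is.numeric(pairs_per_set) || length(pairs_per_set) != 1L ||
      pairs_per_set < 1 || pairs_per_set != round(pairs_per_set)) {
    stop0("`pairs_per_set` must be a positive integer")
  }
  if (!is.numeric(bin_weights) || length(bin_weights) != 5L ||
      any(bin_weights < 0) || abs(sum(bin_weights) - 1) > 1e-9) {
    stop0("`bin_weights` must be 5 non-negative weights summing to 1")
  }
  n_sets <- as.integer(n_sets)
  pairs_per_set <- as.integer(pairs_per_set)
  n <- n_sets * pairs_per_set
  bins <- with_seed(seed, sample.int(5L, n, replace = TRUE, prob = bin_weights))
  bank <- data.frame(
    set_id = rep(seq_len(n_sets), each = pairs_per_set),
    pair_id = rep(seq_len(pairs_per_set), times = n_sets),
    lure_bin = bins
  )
  class(bank) <- c("mst_bank", "data.frame")
  validate_bank(bank)
  bank
}

#' Validate stimulus-bank invariants
#'
#' Checks that lure bins lie in 1..5 and that `(set_id, pair_id)` is unique.
#'
#' @param bank A bank data.frame.
#' @return `bank`, invisibly; errors on violation.
#' @export
validate_bank <- function(bank) {
  bank <- as.data.frame(bank)
  need <- c("set_id", "pair_id", "lure_bin")
  miss <- setdiff(need, names(bank))
  if (length(miss)) stop0("bank is missing columns: ", paste(miss, collapse = ", "))
  if (!all(bank$lure_bin %in% 1:5)) stop0("lure_bin values must be in 1..5")
  key <- pair_key(bank$set_id, bank$pair_id)
  if (anyDuplicated(key)) stop0("(set_id, pair_id) must be unique within a bank")
  invisible(bank)
}

#' Per-set tally of pairs per lure bin
#'
#' @param bank A bank or pair collection.
#' @return A `set x bin` integer matrix (bins 1..5 as columns).
#' @export
bin_counts <- function(bank) {
  bank <- as.data.frame(bank)
  tab <- table(factor(bank$set_id), factor(bank$lure_bin, levels = 1:5))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(set = rownames(tab), lure_bin = 1:5))
  m
}

#' @export
print.mst_bank <- function(x, ...) {
  cat("MST stimulus bank:", nrow(x), "pairs in",
      length(unique(x$set_id)), "set(s)\n")
  print(bin_counts(x))
  invisible(x)
}

#' Split one set into two difficulty-matched halves
#'
#' Within each lure bin the pairs are shuffled and dealt alternately to the
#' two halves, so per-bin counts differ by at most one; odd bins hand their
#' extra pair to whichever half is currently smaller, so the half sizes also
#' differ by at most one.  This mirrors the practice of breaking a stimulus
#' set into half-sized sets equated for difficulty.
#'
#' @param bank_set Pairs from a single set.
#' @param seed Integer seed.
#' @return A list with data.frames `half_a` and `half_b`.
#' @export
split_matched_halves <- function(bank_set, seed = NULL) {
  bank_set <- as.data.frame(bank_set)
  validate_bank(bank_set)
  if (length(unique(bank_set$set_id)) != 1L) {
    stop0("`bank_set` must contain pairs from a single set")
  }
  with_seed(seed, {
    assign_a <- logical(nrow(bank_set))
    imbalance <- 0L # n_a - n_b so far
    for (b in 1:5) {
      idx <- which(bank_set$lure_bin == b)
      if (!length(idx)) next
      idx <- idx[sample.int(length(idx))]
      start_a <- if (length(idx) %% 2L == 1L) imbalance <= 0L else TRUE
      pick <- seq_along(idx) %% 2L == (if (start_a) 1L else 0L)
      assign_a[idx[pick]] <- TRUE
      imbalance <- imbalance + sum(pick) - sum(!pick)
    }
    list(half_a = bank_set[assign_a, , drop = FALSE],
         half_b = bank_set[!assign_a, , drop = FALSE])
  })
}

#' Sample a subset of pairs from a bank
#'
#' Draws `n_pairs` pairs, optionally honouring an exact per-bin count profile
#' and excluding already-used pairs (to support no-repeat session plans).
#'
#' @param bank A stimulus bank.
#' @param n_pairs Number of pairs wanted (ignored when `bin_profile` is a
#'   count vector, whose sum then defines the subset size).
#' @param bin_profile `"proportional"` for a simple random sample, or an
#'   integer vector of length 5 giving exact per-bin counts.
#' @param exclude Optional data.frame with `set_id`, `pair_id` of pairs that
#'   must not be re-used.
#' @param seed Integer seed.
#' @return A data.frame of sampled pairs.
#' @export
sample_subset <- function(bank, n_pairs, bin_profile = "proportional",
                          exclude = NULL, seed = NULL) {
  bank <- as.data.frame(bank)
  validate_bank(bank)
  if (!is.null(exclude) && nrow(as.data.frame(exclude))) {
    exclude <- as.data.frame(exclude)
    drop <- pair_key(bank$set_id, bank$pair_id) %in%
      pair_key(exclude$set_id, exclude$pair_id)
    bank <- bank[!drop, , drop = FALSE]
  }
  with_seed(seed, {
    if (identical(bin_profile, "proportional")) {
      if (!is.numeric(n_pairs) || n_pairs < 1 || n_pairs != round(n_pairs)) {
        stop0("`n_pairs` must be a positive integer")
      }
      if (nrow(bank) < n_pairs) {
        stop0("insufficient pairs: need ", n_pairs, ", have ", nrow(bank),
              " after exclusions")
      }
      out <- bank[sample.int(nrow(bank), n_pairs), , drop = FALSE]
    } else {
      if (!is.numeric(bin_profile) || length(bin_profile) != 5L ||
          any(bin_profile < 0) || any(bin_profile != round(bin_profile))) {
        stop0("`bin_profile` must be \"proportional\" or 5 non-negative counts")
      }
      parts <- vector("list", 5L)
      for (b in 1:5) {
        k <- bin_profile[b]
        if (k == 0) next
        idx <- which(bank$lure_bin == b)
        if (length(idx) < k) {
          stop0("insufficient pairs in lure bin ", b, ": need ", k,
                ", have ", length(idx))
        }
        parts[[b]] <- bank[idx[sample.int(length(idx), k)], , drop = FALSE]
      }
      out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    }
    rownames(out) <- NULL
    out
  })
}
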