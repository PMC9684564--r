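# Independent brute-force oracles. These deliberately re-derive every
# quantity from raw inputs with plain loops, sharing no code path with the
# package implementation.

# Candidate calling: enumerate every (protein, condition) pair directly from
# raw intensities and record fields.
brute_candidates <- function(table, design, q_max = 0.01,
                             min_reps = "all", control_rule = "any") {
  conds <- unique(design$condition)
  out <- list()
  for (cond in conds) {
    bait <- design$sample_id[design$condition == cond &
                               design$pulldown == "bait"]
    ctrl <- design$sample_id[design$condition == cond &
                               design$pulldown == "control"]
    called <- character(0)
    for (i in seq_len(nrow(table$records))) {
      if (table$records$is_reverse[i] || table$records$is_contaminant[i])
        next
      if (!(table$records$q_value[i] < q_max)) next
      n_bait_hits <- 0
      for (s in bait) if (table$intensity[i, s] > 0)
        n_bait_hits <- n_bait_hits + 1
      need <- if (identical(min_reps, "all")) length(bait) else min_reps
      if (n_bait_hits < need) next
      n_ctrl_hits <- 0
      for (s in ctrl) if (table$intensity[i, s] > 0)
        n_ctrl_hits <- n_ctrl_hits + 1
      subtracted <- if (control_rule == "any") n_ctrl_hits >= 1 else
        n_ctrl_hits == length(ctrl)
      if (subtracted) next
      called <- c(called, table$records$group_id[i])
    }
    out[[cond]] <- sort(called)
  }
  out
}

# Venn regions: exhaustive membership-signature count over the union.
brute_regions <- function(sets) {
  conds <- names(sets)
  universe <- sort(unique(unlist(sets)))
  counts <- list()
  n <- length(conds)
  for (bits in seq_len(2^n - 1)) {
    subset <- conds[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0]
    cnt <- 0
    for (id in universe) {
      memb <- conds[vapply(conds, function(cn) id %in% sets[[cn]],
                           logical(1))]
      if (length(memb) == length(subset) && all(memb == subset))
        cnt <- cnt + 1
    }
    counts[[paste(subset, collapse = "&")]] <- cnt
  }
  counts
}

# Hypergeometric upper tail by direct choose() enumeration (exact in double
# precision for N <= 40).
brute_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Pearson r over pairwise-complete observations, from the covariance formula.
brute_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}
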