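#' Log2-transform intensities
#'
#' Returns `log2(intensity)` for every strictly positive intensity; zeros
#' (not detected) become `NA` — no pseudocount is added, so downstream
#' correlations use pairwise-complete observations only.
#'
#' @param table A `protein_group_table`.
#' @return Numeric matrix (protein groups x samples) with `NA` for
#'   undetected cells.
#' @export
log2_intensity <- function(table) {
  m <- table$intensity
  out <- matrix(NA_real_, nrow = nrow(m), ncol = ncol(m),
                dimnames = dimnames(m))
  pos <- m > 0
  out[pos] <- log2(m[pos])
  out
}

#' Pairwise Pearson correlation matrix across samples
#'
#' Computes Pearson r for every sample pair over the proteins quantified
#' (non-missing) in both samples. Pairs sharing fewer than 3 proteins are
#' reported as `NA` (undefined) together with their pair count, never
#' silently dropped.
#'
#' @param values Matrix from [log2_intensity()] (proteins x samples, `NA`
#'   for missing).
#' @param design A `sample_design`; correlations are computed for (and in the
#'   order of) its samples.
#' @param policy Missing-data policy; only `"pairwise_complete"`.
#' @return An object of class `"correlation_matrix"`: list with
#'   `sample_ids`, `r` (symmetric matrix, diagonal 1 where at least 2
#'   observations exist) and `n_pairs` (matrix of shared protein counts).
#' @export
pearson_matrix <- function(values, design, policy = "pairwise_complete") {
  policy <- match.arg(policy)
  missing_s <- setdiff(design$sample_id, colnames(values))
  if (length(missing_s) > 0)
    stop("design sample(s) missing from value matrix: ",
         paste(missing_s, collapse = ", "))
  v <- values[, design$sample_id, drop = FALSE]
  if (ncol(v) < 2) stop("need at least 2 samples")
  n_pairs <- crossprod(!is.na(v))
  storage.mode(n_pairs) <- "integer"
  r <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  r[n_pairs < 3] <- NA_real_
  diag(r) <- ifelse(diag(n_pairs) >= 2, 1, NA_real_)
  structure(list(sample_ids = design$sample_id, r = r, n_pairs = n_pairs,
                 policy = policy),
            class = "correlation_matrix")
}

#' Replicate-concordance QC report
#'
#' Summarizes within-condition replicate correlations separately for bait
#' pull-downs and isotype controls, and flags any bait replicate pair whose
#' Pearson r falls below the threshold (e.g. the 0.93 concordance bar used
#' for pull-down replicates). Undefined pairs (fewer than 3 shared proteins)
#' are listed, not dropped.
#'
#' @param matrix A `correlation_matrix` from [pearson_matrix()].
#' @param design The `sample_design` used to compute it.
#' @param threshold Flagging threshold for bait replicate pairs, in
#'   \[-1, 1\]. Default 0.93.
#' @return List of class `"qc_report"` with `threshold`, `pairs` (data.frame
#'   of within-condition pairs: condition, pulldown, the two samples, r,
#'   n_pairs), `min_bait_r` / `min_control_r` (named per condition),
#'   `flagged` (bait pairs with defined r < threshold), `undefined` (pairs
#'   with undefined r) and `pass`.
#' @export
qc_report <- function(matrix, design, threshold = 0.93) {
  stopifnot(inherits(matrix, "correlation_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < -1 || threshold > 1)
    stop("threshold must be a single value in [-1, 1]")
  rows <- list()
  for (cond in unique(design$condition)) {
    for (pd in c("bait", "control")) {
      ids <- design$sample_id[design$condition == cond &
                                design$pulldown == pd]
      if (length(ids) < 2) next
      cmb <- utils::combn(ids, 2)
      for (j in seq_len(ncol(cmb))) {
        s1 <- cmb[1, j]; s2 <- cmb[2, j]
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, pulldown = pd, sample_1 = s1, sample_2 = s2,
          r = matrix$r[s1, s2], n_pairs = matrix$n_pairs[s1, s2],
          stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  min_by <- function(pd) {
    sub <- pairs[pairs$pulldown == pd, , drop = FALSE]
    if (nrow(sub) == 0) return(stats::setNames(numeric(0), character(0)))
    tapply(sub$r, sub$condition, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  }
  flagged <- pairs[pairs$pulldown == "bait" & !is.na(pairs$r) &
                     pairs$r < threshold, , drop = FALSE]
  undefined <- pairs[is.na(pairs$r), , drop = FALSE]
  structure(
    list(threshold = threshold, pairs = pairs,
         min_bait_r = min_by("bait"), min_control_r = min_by("control"),
         flagged = flagged, undefined = undefined,
         pass = nrow(flagged) == 0),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("replicate QC (threshold %.2f): %s\n", x$threshold,
              if (x$pass) "PASS" else
                sprintf("FAIL (%d bait pair(s) below threshold)",
                        nrow(x$flagged))))
  for (cond in names(x$min_bait_r))
    cat(sprintf("  %s: min bait r = %.3f, min control r = %s\n", cond,
                x$min_bait_r[[cond]],
                if (cond %in% names(x$min_control_r))
                  sprintf("%.3f", x$min_control_r[[cond]]) else "n/a"))
  if (nrow(x$undefined) > 0)
    cat(sprintf("  %d pair(s) undefined (fewer than 3 shared proteins)\n",
                nrow(x$undefined)))
  invisible(x)
}
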