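#' Parameters for candidate-interactor calling
#'
#' @param q_max Quality threshold: protein groups are retained when
#'   `q_value < q_max` (strict). Default 0.01.
#' @param min_bait_replicates `"all"` (default: the protein must be detected
#'   in every bait replicate of the condition) or a positive integer k
#'   (detected in at least k bait replicates).
#' @param control_rule `"any"` (default: a protein detected in at least one
#'   isotype-control replicate of the condition is subtracted) or `"all"`
#'   (subtract only proteins detected in every control replicate).
#' @param presence_rule Only `"intensity_positive"` is implemented: a protein
#'   counts as detected in a sample when its intensity is > 0.
#' @return A list of class `"calling_params"`.
#' @export
calling_params <- function(q_max = 0.01, min_bait_replicates = "all",
                           control_rule = c("any", "all"),
                           presence_rule = "intensity_positive") {
  control_rule <- match.arg(control_rule)
  presence_rule <- match.arg(presence_rule)
  if (!is.numeric(q_max) || length(q_max) != 1 || is.na(q_max) ||
      q_max <= 0 || q_max > 1)
    stop("q_max must be a single value in (0, 1]")
  if (!identical(min_bait_replicates, "all")) {
    k <- suppressWarnings(as.integer(min_bait_replicates))
    if (is.na(k) || k < 1)
      stop("min_bait_replicates must be \"all\" or a positive integer")
    min_bait_replicates <- k
  }
  structure(list(q_max = q_max, min_bait_replicates = min_bait_replicates,
                 control_rule = control_rule, presence_rule = presence_rule),
            class = "calling_params")
}

#' Quality-filter a protein-group table
#'
#' Retains exactly the protein groups with `q_value` strictly below `q_max`;
#' record order is preserved. Boundary values (`q_value == q_max`) are
#' excluded.
#'
#' @param table A `protein_group_table`.
#' @param q_max Threshold in (0, 1].
#' @return The filtered `protein_group_table` (possibly empty).
#' @export
filter_quality <- function(table, q_max = 0.01) {
  if (!is.numeric(q_max) || length(q_max) != 1 || q_max <= 0 || q_max > 1)
    stop("q_max must be a single value in (0, 1]")
  keep <- table$records$q_value < q_max
  subset_pg(table, keep)
}

#' Remove decoy and contaminant protein groups
#'
#' Retains protein groups with both `is_reverse` and `is_contaminant` FALSE.
#'
#' @param table A `protein_group_table`.
#' @return The filtered `protein_group_table`.
#' @export
strip_decoys_contaminants <- function(table) {
  keep <- !table$records$is_reverse & !table$records$is_contaminant
  subset_pg(table, keep)
}

subset_pg <- function(table, keep) {
  records <- table$records[keep, , drop = FALSE]
  rownames(records) <- NULL
  protein_group_table(records,
                      table$intensity[keep, , drop = FALSE])
}

#' Binary detection matrix
#'
#' Binarizes intensities into presence/absence over the samples of a design:
#' under the `"intensity_positive"` rule a protein group is present in a
#' sample iff its intensity there is > 0.
#'
#' @param table A `protein_group_table`; its samples must cover the design's.
#' @param design A `sample_design`.
#' @param rule Presence rule; only `"intensity_positive"`.
#' @return Logical matrix, rows = group identifiers, columns = design
#'   samples in design order.
#' @export
presence_matrix <- function(table, design, rule = "intensity_positive") {
  rule <- match.arg(rule)
  missing_s <- setdiff(design$sample_id, table$sample_ids)
  if (length(missing_s) > 0)
    stop("design sample(s) missing from table: ",
         paste(missing_s, collapse = ", "))
  m <- table$intensity[, design$sample_id, drop = FALSE] > 0
  rownames(m) <- table$records$group_id
  m
}

#' Proteins detected in a condition's isotype controls
#'
#' Under `rule = "any"` returns the identifiers present in at least one
#' control sample of the condition (the default, matching subtraction of any
#' protein ever seen in the respective isotype controls); under `"all"`, the
#' identifiers present in every control sample of the condition.
#'
#' @param matrix Detection matrix from [presence_matrix()].
#' @param design A `sample_design`.
#' @param condition Condition label.
#' @param rule `"any"` or `"all"`.
#' @return Character vector of group identifiers.
#' @export
control_detected <- function(matrix, design, condition,
                             rule = c("any", "all")) {
  rule <- match.arg(rule)
  ctrl <- design$sample_id[design$condition == condition &
                             design$pulldown == "control"]
  if (length(ctrl) == 0)
    stop("condition has no control samples: ", condition)
  hits <- rowSums(matrix[, ctrl, drop = FALSE])
  need <- if (rule == "any") 1L else length(ctrl)
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- character(0)
  ids[hits >= need]
}

#' Proteins detected consistently across a condition's bait replicates
#'
#' Under `min_reps = "all"` returns the identifiers present in every bait
#' sample of the condition; under an integer k, those present in at least k
#' bait samples.
#'
#' @param matrix Detection matrix from [presence_matrix()].
#' @param design A `sample_design`.
#' @param condition Condition label.
#' @param min_reps `"all"` or a positive integer not exceeding the number of
#'   bait samples of the condition.
#' @return Character vector of group identifiers.
#' @export
replicate_consistent <- function(matrix, design, condition,
                                 min_reps = "all") {
  bait <- design$sample_id[design$condition == condition &
                             design$pulldown == "bait"]
  if (length(bait) == 0)
    stop("condition has no bait samples: ", condition)
  if (identical(min_reps, "all")) {
    k <- length(bait)
  } else {
    k <- as.integer(min_reps)
    if (is.na(k) || k < 1)
      stop("min_reps must be \"all\" or a positive integer")
    if (k > length(bait))
      stop("min_reps (", k, ") exceeds the number of bait samples (",
           length(bait), ") for condition ", condition)
  }
  hits <- rowSums(matrix[, bait, drop = FALSE])
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- character(0)
  ids[hits >= k]
}

#' Call candidate bait interactors per condition
#'
#' The full presence/absence classification: protein groups are
#' quality-filtered (`q_value < q_max`), decoy and contaminant rows are
#' removed, and per condition a protein is a candidate interactor iff it is
#' detected in the required number of bait replicates (default: all) and not
#' detected in the condition's isotype controls (default: subtracted when
#' seen in any control replicate). The bait itself is subject to the same
#' rules, with no special-casing. Filters are applied before binarization, so
#' a decoy detected in a control cannot mask a real protein. Control
#' subtraction is per condition, never pooled.
#'
#' @param table A `protein_group_table`.
#' @param design A `sample_design` with at least one condition carrying both
#'   pull-down types.
#' @param params A [calling_params()].
#' @return An object of class `"candidate_sets"`: list with `sets` (named
#'   list, condition -> character vector of group identifiers, sorted) and
#'   `params`.
#' @export
call_candidates <- function(table, design, params = calling_params()) {
  stopifnot(inherits(params, "calling_params"))
  filtered <- strip_decoys_contaminants(filter_quality(table, params$q_max))
  m <- presence_matrix(filtered, design, params$presence_rule)
  conditions <- unique(design$condition)
  sets <- lapply(conditions, function(cond) {
    consistent <- replicate_consistent(m, design, cond,
                                       params$min_bait_replicates)
    in_ctrl <- control_detected(m, design, cond, params$control_rule)
    sort(setdiff(consistent, in_ctrl))
  })
  names(sets) <- conditions
  structure(list(sets = sets, params = params), class = "candidate_sets")
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat("candidate_sets:\n")
  for (cond in names(x$sets))
    cat(sprintf("  %s: %d candidates\n", cond, length(x$sets[[cond]])))
  cat(sprintf("  (q_max = %g, min bait replicates = %s, control rule = %s)\n",
              x$params$q_max, as.character(x$params$min_bait_replicates),
              x$params$control_rule))
  invisible(x)
}
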