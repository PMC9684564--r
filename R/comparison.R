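#' @keywords internal
as_condition_sets <- function(sets) {
  if (inherits(sets, "candidate_sets")) sets <- sets$sets
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a candidate_sets object or a named list of ",
         "identifier vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate condition labels in sets")
  lapply(sets, function(s) unique(as.character(s)))
}

#' Compare candidate sets across conditions
#'
#' Partitions the union of all candidate sets by exact condition-membership
#' signature (the regions of a Venn diagram). All `2^n - 1` non-empty
#' membership patterns are reported, including zero-count regions, so the
#' output shape is deterministic.
#'
#' @param sets A `candidate_sets` object or a named list (condition ->
#'   character vector) with at least two conditions.
#' @return An object of class `"comparison_result"`: list with
#'   `conditions`, `sets`, `membership` (named list: identifier -> conditions
#'   containing it), `region_counts` (data.frame: `region` label,
#'   `conditions` list column, `n_conditions`, `count`, `members` list
#'   column) and `common_all` (sorted intersection of all sets).
#' @export
compare_conditions <- function(sets) {
  sets <- as_condition_sets(sets)
  if (length(sets) < 2)
    stop("need at least 2 condition sets to compare")
  conditions <- names(sets)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  in_set <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  in_set <- matrix(in_set, nrow = length(universe),
                   dimnames = list(universe, conditions))
  membership <- apply(in_set, 1, function(row) conditions[row],
                      simplify = FALSE)

  n <- length(conditions)
  subsets <- lapply(seq_len(2^n - 1), function(bits) {
    conditions[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0]
  })
  sig <- vapply(membership, paste, character(1), collapse = "&")
  region_label <- vapply(subsets, paste, character(1), collapse = "&")
  members <- lapply(region_label, function(lab) universe[sig == lab])
  region_counts <- data.frame(
    region = region_label,
    n_conditions = lengths(subsets),
    count = lengths(members),
    stringsAsFactors = FALSE
  )
  region_counts$conditions <- subsets
  region_counts$members <- members

  structure(
    list(conditions = conditions, sets = sets, membership = membership,
         region_counts = region_counts,
         common_all = sort(Reduce(intersect, sets))),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison_result: %d conditions, union of %d identifiers\n",
              length(x$conditions), length(x$membership)))
  cat(sprintf("  common to all conditions: %d\n", length(x$common_all)))
  nonzero <- x$region_counts[x$region_counts$count > 0,
                             c("region", "count")]
  for (i in seq_len(nrow(nonzero)))
    cat(sprintf("  %-40s %d\n", nonzero$region[i], nonzero$count[i]))
  invisible(x)
}

#' Identifiers unique to a group of conditions
#'
#' Returns the identifiers present in every condition of `group` and absent
#' from every other condition: `intersect(group sets) \ union(other sets)`.
#' With `group` equal to all conditions this degenerates to the common core.
#'
#' @param sets A `candidate_sets`, named list, or `comparison_result`.
#' @param group Non-empty character vector of condition labels.
#' @return Sorted character vector of identifiers.
#' @export
unique_to <- function(sets, group) {
  if (inherits(sets, "comparison_result")) sets <- sets$sets
  sets <- as_condition_sets(sets)
  if (length(group) == 0) stop("group must be non-empty")
  unknown <- setdiff(group, names(sets))
  if (length(unknown) > 0)
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  core <- Reduce(intersect, sets[group])
  others <- setdiff(names(sets), group)
  sort(setdiff(core, unlist(sets[others], use.names = FALSE)))
}

#' Consistency check for a group core
#'
#' For a comparison with exactly one condition outside `group`, the group
#' core must split exactly into the all-condition common core and the
#' group-unique set: `intersect(group) = common_all + unique_to(group)`,
#' with the two parts disjoint (the identity behind tallies such as
#' "common-to-all + cancer-unique = cancer-core").
#'
#' @param result A `comparison_result`.
#' @param group Character vector of condition labels leaving exactly one
#'   condition out.
#' @return List of class `"consistency_report"` with `pass`, the three
#'   counts, and `discrepancy` (identifiers breaking the identity, empty on
#'   pass).
#' @export
consistency_check <- function(result, group) {
  stopifnot(inherits(result, "comparison_result"))
  out_of_group <- setdiff(result$conditions, group)
  if (length(out_of_group) != 1)
    stop("consistency_check needs exactly one non-group condition; got ",
         length(out_of_group))
  core <- sort(Reduce(intersect, result$sets[group]))
  uniq <- unique_to(result, group)
  common <- result$common_all
  recombined <- sort(union(common, uniq))
  disjoint <- length(intersect(common, uniq)) == 0
  discrepancy <- sort(union(setdiff(core, recombined),
                            setdiff(recombined, core)))
  structure(
    list(pass = disjoint && length(discrepancy) == 0,
         n_group_core = length(core), n_common_all = length(common),
         n_unique = length(uniq), disjoint = disjoint,
         discrepancy = discrepancy, group = group),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency check for group {%s}: %s\n",
              paste(x$group, collapse = ", "),
              if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  group core %d = common to all %d + group-unique %d\n",
              x$n_group_core, x$n_common_all, x$n_unique))
  if (length(x$discrepancy) > 0)
    cat("  discrepancy:", paste(x$discrepancy, collapse = ", "), "\n")
  invisible(x)
}

#' Overlap statistics between two identifier sets
#'
#' Intersection count, percentage of each side covered, and Jaccard index,
#' as used when comparing a called interactor list against a reference
#' interactome (e.g. a BioGRID, BioPlex or STRING export). Percentages over
#' an empty side are reported as 0 with `degenerate = TRUE`.
#'
#' @param query Character vector (deduplicated internally).
#' @param reference Character vector (deduplicated internally).
#' @return List of class `"overlap_stats"` with `count`, `pct_of_query`,
#'   `pct_of_reference`, `jaccard`, `n_query`, `n_reference`, `degenerate`.
#' @export
overlap_stats <- function(query, reference) {
  query <- unique(as.character(query))
  reference <- unique(as.character(reference))
  count <- length(intersect(query, reference))
  n_union <- length(union(query, reference))
  degenerate <- length(query) == 0 || length(reference) == 0
  structure(
    list(count = count,
         pct_of_query = if (length(query) == 0) 0 else
           100 * count / length(query),
         pct_of_reference = if (length(reference) == 0) 0 else
           100 * count / length(reference),
         jaccard = if (n_union == 0) 0 else count / n_union,
         n_query = length(query), n_reference = length(reference),
         degenerate = degenerate),
    class = "overlap_stats"
  )
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "overlap: %d shared (%.1f%% of %d query, %.1f%% of %d reference), Jaccard %.3f%s\n",
    x$count, x$pct_of_query, x$n_query, x$pct_of_reference, x$n_reference,
    x$jaccard, if (x$degenerate) " [degenerate: empty side]" else ""))
  invisible(x)
}

#' Export Venn region counts (and optionally a figure)
#'
#' Writes the full region table (all `2^n - 1` membership signatures,
#' including zero counts) as TSV. When `fig_path` is given and the comparison
#' has 2-4 conditions, a base-graphics Venn figure (circles for 2-3 sets,
#' ellipses for 4) is written as PDF; for more than 4 sets the figure is
#' skipped with a warning and only counts are written.
#'
#' @param result A `comparison_result`.
#' @param path Output TSV path.
#' @param fig_path Optional PDF path for the diagram.
#' @return Invisibly, the region-count data.frame that was written.
#' @export
venn_export <- function(result, path, fig_path = NULL) {
  stopifnot(inherits(result, "comparison_result"))
  rc <- result$region_counts
  out <- data.frame(
    region = rc$region, n_conditions = rc$n_conditions, count = rc$count,
    members = vapply(rc$members, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(fig_path)) {
    n <- length(result$conditions)
    if (n > 4) {
      warning("Venn figure supports at most 4 sets (got ", n,
              "); wrote counts only")
    } else {
      grDevices::pdf(fig_path, width = 7, height = 7)
      on.exit(grDevices::dev.off(), add = TRUE)
      draw_venn(result)
    }
  }
  invisible(out)
}

# region label lookup: count for an exact membership signature
region_count <- function(result, conds) {
  lab <- paste(result$conditions[result$conditions %in% conds],
               collapse = "&")
  result$region_counts$count[match(lab, result$region_counts$region)]
}

ellipse_xy <- function(cx, cy, a, b, angle) {
  t <- seq(0, 2 * pi, length.out = 181)
  x <- a * cos(t); y <- b * sin(t)
  list(x = cx + x * cos(angle) - y * sin(angle),
       y = cy + x * sin(angle) + y * cos(angle))
}

draw_venn <- function(result) {
  conds <- result$conditions
  n <- length(conds)
  graphics::plot.new()
  graphics::plot.window(xlim = c(-3, 3), ylim = c(-3, 3), asp = 1)
  graphics::title(main = sprintf("Candidate interactor overlap (%d sets)", n))
  cols <- grDevices::adjustcolor(c("#1b9e77", "#d95f02", "#7570b3",
                                   "#e7298a")[seq_len(n)], alpha.f = 0.35)
  if (n == 2) {
    shapes <- list(ellipse_xy(-0.7, 0, 1.4, 1.4, 0),
                   ellipse_xy(0.7, 0, 1.4, 1.4, 0))
    label_at <- list(`1` = c(-1.4, 0), `2` = c(1.4, 0), `12` = c(0, 0))
    name_at <- list(c(-1.6, 1.7), c(1.6, 1.7))
  } else if (n == 3) {
    shapes <- list(ellipse_xy(-0.8, -0.5, 1.5, 1.5, 0),
                   ellipse_xy(0.8, -0.5, 1.5, 1.5, 0),
                   ellipse_xy(0, 0.9, 1.5, 1.5, 0))
    label_at <- list(`1` = c(-1.4, -0.9), `2` = c(1.4, -0.9),
                     `3` = c(0, 1.7), `12` = c(0, -0.9),
                     `13` = c(-0.85, 0.55), `23` = c(0.85, 0.55),
                     `123` = c(0, 0))
    name_at <- list(c(-2.1, -1.9), c(2.1, -1.9), c(0, 2.6))
  } else {
    # classic 4-ellipse layout
    shapes <- list(ellipse_xy(-0.9, -0.2, 2.1, 1.1, pi / 4),
                   ellipse_xy(-0.3, 0.25, 2.1, 1.1, pi / 4),
                   ellipse_xy(0.3, 0.25, 2.1, 1.1, -pi / 4),
                   ellipse_xy(0.9, -0.2, 2.1, 1.1, -pi / 4))
    label_at <- list(
      `1` = c(-2.0, -0.9), `2` = c(-1.1, 1.3), `3` = c(1.1, 1.3),
      `4` = c(2.0, -0.9),
      `12` = c(-1.5, 0.4), `13` = c(-1.1, -1.6), `14` = c(0, -2.1),
      `23` = c(0, 1.0), `24` = c(1.1, -1.6), `34` = c(1.5, 0.4),
      `123` = c(-0.8, 0.3), `124` = c(-0.55, -1.5), `134` = c(0.55, -1.5),
      `234` = c(0.8, 0.3), `1234` = c(0, -0.7))
    name_at <- list(c(-2.8, 0.9), c(-1.3, 2.2), c(1.3, 2.2), c(2.8, 0.9))
  }
  for (i in seq_len(n)) {
    graphics::polygon(shapes[[i]]$x, shapes[[i]]$y, col = cols[i],
                      border = "grey30")
    graphics::text(name_at[[i]][1], name_at[[i]][2], conds[i], font = 2)
  }
  for (key in names(label_at)) {
    idx <- as.integer(strsplit(key, "")[[1]])
    cnt <- region_count(result, conds[idx])
    graphics::text(label_at[[key]][1], label_at[[key]][2], cnt)
  }
  invisible(NULL)
}
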