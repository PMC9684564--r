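#' One-sided Fisher's exact overrepresentation p-value
#'
#' Probability, under the hypergeometric null, of drawing at least `k`
#' members of a term of size `K` when sampling `n` genes without replacement
#' from a background of size `N`:
#' `p = sum_{i = k..min(n, K)} C(K, i) C(N - K, n - i) / C(N, n)`.
#' Evaluated in log space via the hypergeometric upper tail, so it is stable
#' for large backgrounds. Equals the one-sided (greater) Fisher's exact test
#' on the corresponding 2x2 table. All arguments are vectorized.
#'
#' @param k Query hits in the term (0 <= k <= n, k <= K).
#' @param n Query size.
#' @param K Term (background annotation) size.
#' @param N Background size (n <= N, K <= N).
#' @return p-value(s) in \[0, 1\].
#' @export
#' @examples
#' fisher_overrepresentation(5, 5, 5, 10) # 1 / choose(10, 5)
fisher_overrepresentation <- function(k, n, K, N) {
  nn <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(as.numeric(k), nn); n <- rep_len(as.numeric(n), nn)
  K <- rep_len(as.numeric(K), nn); N <- rep_len(as.numeric(N), nn)
  if (any(k < 0 | k > n | n > N | k > K | K > N))
    stop("bounds violated: need 0 <= k <= n <= N and k <= K <= N")
  pmin(1, stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Fisher's-exact overrepresentation over an annotation map
#'
#' Tests every term of the annotation for overrepresentation in a query gene
#' set against a background (reference) gene set. Query genes outside the
#' background are dropped (with a message reporting the count); term members
#' are restricted to the background; terms with no background member are
#' skipped. Multiple-testing correction is applied within each ontology
#' category separately. Gene identity is case-sensitive exact string match.
#'
#' @param query Character vector of gene identifiers.
#' @param annotation An `annotation_map` from [read_gmt()].
#' @param background Character vector: the reference gene universe (e.g. all
#'   annotated genes of the organism). Never defaults to the query.
#' @param correction `"BH"` (Benjamini-Hochberg, default), `"bonferroni"`, or
#'   `"none"` (fdr column then equals the raw p-value).
#' @return Data.frame of class `"enrichment_result"`, one row per tested
#'   term, sorted by ascending p-value (ties by term_id), with columns
#'   `term_id`, `term_name`, `category`, `k`, `n`, `K`, `N`, `expected`,
#'   `fold_enrichment`, `p_value`, `fdr`.
#' @export
enrich_all <- function(query, annotation, background,
                       correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(annotation, "annotation_map"))
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background must be non-empty")
  query <- unique(as.character(query))
  dropped <- setdiff(query, background)
  if (length(dropped) > 0)
    message(length(dropped), " query gene(s) not in background; dropped")
  query <- intersect(query, background)
  if (length(query) == 0)
    stop("no query genes remain after restriction to the background")

  N <- length(background)
  n <- length(query)
  members_bg <- lapply(annotation$members, intersect, background)
  keep <- lengths(members_bg) > 0
  K <- lengths(members_bg)[keep]
  k <- vapply(members_bg[keep], function(m) length(intersect(m, query)),
              integer(1))
  res <- data.frame(
    term_id = annotation$term_id[keep],
    term_name = annotation$term_name[keep],
    category = annotation$category[keep],
    k = k, n = n, K = K, N = N,
    expected = n * K / N,
    fold_enrichment = (k / n) / (K / N),
    p_value = fisher_overrepresentation(k, n, K, N),
    stringsAsFactors = FALSE
  )
  method <- c(BH = "BH", bonferroni = "bonferroni", none = "none")[correction]
  res$fdr <- stats::ave(res$p_value, res$category,
                        FUN = function(p) stats::p.adjust(p, method = method))
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Top enriched terms of one ontology category
#'
#' Sorts the results of a category by ascending p-value (ties broken by
#' ascending term_id) and returns the first `n`; fewer are returned when the
#' category holds fewer tested terms.
#'
#' @param results An `enrichment_result` from [enrich_all()].
#' @param n Number of terms to return (default 10).
#' @param category Ontology category to rank within; `NULL` ranks across all.
#' @return The ranked subset, same columns as `results`.
#' @export
top_terms <- function(results, n = 10, category = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive integer")
  if (!is.null(category))
    results <- results[results$category == category, , drop = FALSE]
  results <- results[order(results$p_value, results$term_id), , drop = FALSE]
  out <- utils::head(results, n)
  rownames(out) <- NULL
  out
}
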