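#' Column dialect for MaxQuant-style protein-group tables
#'
#' Names the columns of a tab-delimited protein-group table. Defaults match
#' the `proteinGroups.txt` written by MaxQuant 1.5.x: grouped accessions in
#' "Majority protein IDs", identification q-value in "Q-value", decoy and
#' contaminant flags marked with "+" in "Reverse" / "Potential contaminant",
#' and one intensity column per sample named "Intensity <sample>".
#'
#' @param accessions Column holding semicolon-delimited protein accessions.
#' @param gene_name Column holding the gene name (may be blank per row).
#' @param q_value Column holding the identification q-value in \[0, 1\].
#' @param reverse Column flagging reverse (decoy) hits with "+".
#' @param contaminant Column flagging common contaminants with "+".
#' @param intensity_prefix Prefix of per-sample intensity columns; the sample
#'   identifier is the remainder of the column name after the prefix.
#' @param molecular_weight Optional column with the molecular weight in kDa;
#'   parsed when present, `NA` otherwise.
#' @return A list of class `"pg_dialect"`.
#' @export
#' @examples
#' maxquant_dialect()
maxquant_dialect <- function(accessions = "Majority protein IDs",
                             gene_name = "Gene names",
                             q_value = "Q-value",
                             reverse = "Reverse",
                             contaminant = "Potential contaminant",
                             intensity_prefix = "Intensity ",
                             molecular_weight = "Mol. weight [kDa]") {
  structure(
    list(accessions = accessions, gene_name = gene_name, q_value = q_value,
         reverse = reverse, contaminant = contaminant,
         intensity_prefix = intensity_prefix,
         molecular_weight = molecular_weight),
    class = "pg_dialect"
  )
}

#' Construct a protein-group table
#'
#' The container used throughout the pipeline: one row per protein group with
#' its accessions, gene name, q-value, decoy/contaminant flags, and a
#' non-negative intensity per sample (0 means not detected). The group
#' identifier used for all cross-table matching is the leading (first
#' majority) accession.
#'
#' @param records A data.frame with columns `group_id` (unique, non-empty),
#'   `accessions` (list of character vectors, each non-empty), `gene_name`,
#'   `q_value` (in \[0, 1\]), `is_reverse`, `is_contaminant` (logical) and
#'   `molecular_weight_kda` (numeric, `NA` allowed).
#' @param intensity Numeric matrix, rows matching `records$group_id`, one
#'   column per sample; all values must be finite and >= 0.
#' @return An object of class `"protein_group_table"`: a list with elements
#'   `records`, `intensity` and `sample_ids`.
#' @export
protein_group_table <- function(records, intensity) {
  stopifnot(is.data.frame(records), is.matrix(intensity))
  needed <- c("group_id", "accessions", "gene_name", "q_value",
              "is_reverse", "is_contaminant", "molecular_weight_kda")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0)
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) != nrow(intensity))
    stop("records and intensity disagree on the number of protein groups")
  if (anyDuplicated(records$group_id))
    stop("duplicate group_id: ",
         paste(unique(records$group_id[duplicated(records$group_id)]),
               collapse = ", "))
  if (any(lengths(records$accessions) == 0))
    stop("every protein group must have at least one accession")
  if (any(!is.finite(records$q_value) | records$q_value < 0 |
          records$q_value > 1))
    stop("q_value must lie in [0, 1]")
  if (nrow(intensity) > 0 && ncol(intensity) > 0 &&
      any(!is.finite(intensity) | intensity < 0))
    stop("intensities must be finite and non-negative")
  if (is.null(colnames(intensity)))
    stop("intensity matrix must have sample ids as column names")
  rownames(intensity) <- records$group_id
  structure(
    list(records = records, intensity = intensity,
         sample_ids = colnames(intensity)),
    class = "protein_group_table"
  )
}

#' @export
print.protein_group_table <- function(x, ...) {
  cat(sprintf("protein_group_table: %d protein groups x %d samples\n",
              nrow(x$records), length(x$sample_ids)))
  cat(sprintf("  decoys: %d, contaminants: %d\n",
              sum(x$records$is_reverse), sum(x$records$is_contaminant)))
  invisible(x)
}

#' Number of protein groups in a table
#' @param x A `protein_group_table`.
#' @return Integer count of protein groups (rows).
#' @export
n_groups <- function(x) nrow(x$records)

#' Read a MaxQuant-style protein-group table
#'
#' Parses a tab-delimited protein-group table into a
#' [protein_group_table()]. Semicolon-delimited accession cells are split in
#' order; flag cells equal to `"+"` map to `TRUE` and empty cells to `FALSE`;
#' blank intensity cells map to 0 (not detected). Sample identifiers are the
#' intensity column names with the dialect prefix removed, in file column
#' order.
#'
#' @param path Path to the tab-delimited file (UTF-8, header row required).
#' @param dialect A [maxquant_dialect()] naming the columns.
#' @return A `protein_group_table`.
#' @export
read_protein_groups <- function(path, dialect = maxquant_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("format error: empty file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", na.strings = NULL,
                          fileEncoding = "UTF-8")
  mandatory <- c(dialect$accessions, dialect$gene_name, dialect$q_value,
                 dialect$reverse, dialect$contaminant)
  absent <- setdiff(mandatory, names(df))
  if (length(absent) > 0)
    stop("format error: missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  int_cols <- names(df)[startsWith(names(df), dialect$intensity_prefix) &
                          nchar(names(df)) > nchar(dialect$intensity_prefix)]
  if (length(int_cols) == 0)
    stop("format error: no intensity columns with prefix '",
         dialect$intensity_prefix, "'")
  sample_ids <- substring(int_cols, nchar(dialect$intensity_prefix) + 1L)

  parse_flag <- function(x, col) {
    bad <- !(x %in% c("+", ""))
    if (any(bad))
      stop("row ", which(bad)[1], ": invalid flag value '", x[bad][1],
           "' in column '", col, "' (expected '+' or empty)")
    x == "+"
  }
  parse_num <- function(x, col, blank_to = NA_real_) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    out[x == ""] <- blank_to
    bad <- is.na(out) & x != ""
    if (any(bad))
      stop("row ", which(bad)[1], ": non-numeric value '", x[bad][1],
           "' in column '", col, "'")
    out
  }

  q <- parse_num(df[[dialect$q_value]], dialect$q_value)
  if (anyNA(q))
    stop("row ", which(is.na(q))[1], ": missing q-value")
  acc <- lapply(strsplit(df[[dialect$accessions]], ";", fixed = TRUE),
                trimws)
  empty_acc <- vapply(acc, function(a) length(a) == 0 || all(a == ""),
                      logical(1))
  if (any(empty_acc))
    stop("row ", which(empty_acc)[1], ": empty accession cell")
  mw <- if (!is.null(dialect$molecular_weight) &&
            dialect$molecular_weight %in% names(df)) {
    parse_num(df[[dialect$molecular_weight]], dialect$molecular_weight)
  } else {
    rep(NA_real_, nrow(df))
  }

  intensity <- matrix(0, nrow = nrow(df), ncol = length(int_cols),
                      dimnames = list(NULL, sample_ids))
  for (j in seq_along(int_cols)) {
    v <- parse_num(df[[int_cols[j]]], int_cols[j], blank_to = 0)
    if (any(v < 0))
      stop("row ", which(v < 0)[1], ": negative intensity in column '",
           int_cols[j], "'")
    intensity[, j] <- v
  }

  records <- data.frame(
    group_id = vapply(acc, `[`, character(1), 1L),
    gene_name = df[[dialect$gene_name]],
    q_value = q,
    is_reverse = parse_flag(df[[dialect$reverse]], dialect$reverse),
    is_contaminant = parse_flag(df[[dialect$contaminant]],
                                dialect$contaminant),
    molecular_weight_kda = mw,
    stringsAsFactors = FALSE
  )
  records$accessions <- acc
  protein_group_table(records, intensity)
}

#' Write a protein-group table in the MaxQuant dialect
#'
#' Inverse of [read_protein_groups()]: emits a tab-delimited file that
#' re-parses with zero row errors. Undetected intensities are written as 0.
#'
#' @param table A `protein_group_table`.
#' @param path Output path.
#' @param dialect A [maxquant_dialect()] naming the output columns.
#' @return Invisibly, `path`.
#' @export
write_protein_groups <- function(table, path, dialect = maxquant_dialect()) {
  rec <- table$records
  out <- data.frame(
    a = vapply(rec$accessions, paste, character(1), collapse = ";"),
    g = rec$gene_name,
    q = format(rec$q_value, digits = 15, scientific = FALSE, trim = TRUE),
    r = ifelse(rec$is_reverse, "+", ""),
    c = ifelse(rec$is_contaminant, "+", ""),
    m = ifelse(is.na(rec$molecular_weight_kda), "",
               format(rec$molecular_weight_kda, digits = 10, trim = TRUE)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- c(dialect$accessions, dialect$gene_name, dialect$q_value,
                  dialect$reverse, dialect$contaminant,
                  dialect$molecular_weight)
  ints <- apply(table$intensity, 2, function(v)
    ifelse(v == 0, "0", format(v, digits = 15, scientific = FALSE,
                               trim = TRUE)))
  ints <- matrix(ints, nrow = nrow(rec),
                 dimnames = list(NULL, paste0(dialect$intensity_prefix,
                                              table$sample_ids)))
  out <- cbind(out, as.data.frame(ints, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a sample design
#'
#' Maps each sample to its condition (e.g. cell line), pull-down type (bait
#' IP or isotype control) and replicate index.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param condition Character vector of condition labels.
#' @param pulldown Character vector, each `"bait"` or `"control"`.
#' @param replicate Positive integer replicate indices, distinct within each
#'   (condition, pulldown) pair.
#' @return A data.frame of class `"sample_design"`.
#' @export
sample_design <- function(sample_id, condition, pulldown, replicate) {
  pulldown <- tolower(as.character(pulldown))
  if (!all(pulldown %in% c("bait", "control")))
    stop("pulldown values must be 'bait' or 'control'; got: ",
         paste(setdiff(unique(pulldown), c("bait", "control")),
               collapse = ", "))
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  replicate <- as.integer(replicate)
  if (any(is.na(replicate) | replicate < 1))
    stop("replicate indices must be positive integers")
  d <- data.frame(sample_id = as.character(sample_id),
                  condition = as.character(condition),
                  pulldown = pulldown, replicate = replicate,
                  stringsAsFactors = FALSE)
  key <- paste(d$condition, d$pulldown, d$replicate)
  if (anyDuplicated(key))
    stop("replicate indices must be distinct within a (condition, pulldown) ",
         "pair: ", key[duplicated(key)][1])
  has_bait <- tapply(d$pulldown == "bait", d$condition, any)
  if (!all(has_bait))
    stop("condition(s) without a bait sample: ",
         paste(names(has_bait)[!has_bait], collapse = ", "))
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample design table
#'
#' Tab-delimited file with columns `sample_id`, `condition`, `pulldown`
#' (case-insensitive; aliases such as "IgG" may be mapped to control) and
#' `replicate`.
#'
#' @param path Path to the design file.
#' @param aliases Named character vector mapping extra (lower-cased) pulldown
#'   labels to `"bait"` or `"control"`; defaults map "igg" and "isotype" to
#'   control and "ip" to bait.
#' @return A `sample_design`.
#' @export
read_design <- function(path,
                        aliases = c(igg = "control", isotype = "control",
                                    ip = "bait")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", fileEncoding = "UTF-8")
  needed <- c("sample_id", "condition", "pulldown", "replicate")
  absent <- setdiff(needed, names(df))
  if (length(absent) > 0)
    stop("format error: missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  pd <- tolower(trimws(df$pulldown))
  mapped <- ifelse(pd %in% names(aliases), unname(aliases[pd]), pd)
  unknown <- setdiff(unique(mapped), c("bait", "control"))
  if (length(unknown) > 0)
    stop("unknown pulldown value(s): ", paste(unknown, collapse = ", "))
  rep_i <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_i))
    stop("non-integer replicate value: ",
         df$replicate[which(is.na(rep_i))[1]])
  sample_design(trimws(df$sample_id), trimws(df$condition), mapped, rep_i)
}

#' Write a sample design table
#' @param design A `sample_design`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GMT annotation file
#'
#' Standard GMT: one term per line, tab-delimited as
#' `term_id <tab> description <tab> gene1 <tab> gene2 ...`. Duplicate member
#' genes within a line are deduplicated. An ontology category
#' (`"biological_process"`, `"cellular_component"`, `"molecular_function"`,
#' `"other"`) can be encoded per term by prefixing the description with
#' `"BP|"`, `"CC|"` or `"MF|"`; otherwise `default_category` is used.
#'
#' @param path Path to the GMT file.
#' @param default_category Category assigned to terms without a prefix.
#' @return An `annotation_map`: a data.frame with columns `term_id`,
#'   `term_name`, `category` and `members` (list of character vectors).
#' @export
read_gmt <- function(path, default_category = "other") {
  default_category <- match.arg(default_category,
                                c("other", "biological_process",
                                  "cellular_component",
                                  "molecular_function"))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("format error: empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short))
    stop("format error: line ", which(short)[1],
         " has fewer than 3 tab-delimited fields")
  term_id <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(term_id))
    stop("duplicate term_id: ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "))
  desc <- vapply(parts, `[`, character(1), 2L)
  prefix <- sub("\\|.*$", "", desc)
  category <- rep(default_category, length(desc))
  category[prefix == "BP"] <- "biological_process"
  category[prefix == "CC"] <- "cellular_component"
  category[prefix == "MF"] <- "molecular_function"
  term_name <- ifelse(prefix %in% c("BP", "CC", "MF"),
                      sub("^[A-Z]{2}\\|", "", desc), desc)
  members <- lapply(parts, function(p) {
    m <- unique(trimws(p[-(1:2)]))
    m[nzchar(m)]
  })
  empty <- lengths(members) == 0
  if (any(empty))
    stop("term with no members after deduplication: ",
         term_id[which(empty)[1]])
  out <- data.frame(term_id = term_id, term_name = term_name,
                    category = category, stringsAsFactors = FALSE)
  out$members <- members
  class(out) <- c("annotation_map", "data.frame")
  out
}

#' Write an annotation map as GMT
#'
#' Categories are encoded as `"BP|"` / `"CC|"` / `"MF|"` description prefixes
#' so that [read_gmt()] round-trips them.
#'
#' @param annotation An `annotation_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(annotation, path) {
  pre <- c(biological_process = "BP|", cellular_component = "CC|",
           molecular_function = "MF|", other = "")
  lines <- vapply(seq_len(nrow(annotation)), function(i) {
    paste(c(annotation$term_id[i],
            paste0(pre[[annotation$category[i]]], annotation$term_name[i]),
            annotation$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a plain identifier list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; surrounding whitespace is stripped; duplicates are removed. Used
#' for reference interactome lists (e.g. a BioGRID export).
#'
#' @param path Path to the text file.
#' @return Character vector of unique identifiers. Emits a warning (not an
#'   error) when the result is empty.
#' @export
read_id_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(lines)
  if (length(ids) == 0)
    warning("identifier list is empty: ", path)
  ids
}

#' Write a per-condition candidate interactor table
#'
#' Emits a tab-delimited table with columns `accession`, `gene_name` and
#' `molecular_weight_kda`, one row per candidate, sorted by accession for
#' deterministic output (analogous to the per-cell-line interactor lists of
#' an IP-MS study's supplementary tables).
#'
#' @param candidates Character vector of group identifiers; each must be a
#'   `group_id` of `table`.
#' @param table The `protein_group_table` the candidates were called from.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidate_table <- function(candidates, table, path) {
  candidates <- unique(as.character(candidates))
  idx <- match(candidates, table$records$group_id)
  if (anyNA(idx))
    stop("candidate not present in table: ",
         paste(candidates[is.na(idx)], collapse = ", "))
  out <- data.frame(
    accession = table$records$group_id[idx],
    gene_name = table$records$gene_name[idx],
    molecular_weight_kda = table$records$molecular_weight_kda[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$accession), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a candidate interactor table written by [write_candidate_table()]
#' @param path Path to the TSV.
#' @return Data.frame with columns `accession`, `gene_name`,
#'   `molecular_weight_kda`.
#' @export
read_candidate_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Published common-core interactor table of the karyopherin beta-1 study
#'
#' The study's printed table of proteins co-immunoprecipitating with the
#' nuclear import receptor Kpn-beta-1 in all four cell lines examined
#' (hTERT-RPE1, HeLa, WHCO5, KYSE30): the bait itself plus 38 common binding
#' partners, with accession, protein name, gene name and molecular weight.
#'
#' @return Data.frame with columns `group`, `accession`, `protein_name`,
#'   `gene_name`, `molecular_weight_kda`.
#' @seealso [kpnb1_cancer_unique()]
#' @export
kpnb1_common_core <- function() {
  read_candidate_table(system.file("extdata", "kpnb1_common_core.tsv",
                                   package = "apmscall", mustWork = TRUE))
}

#' Published cancer-unique interactor table of the karyopherin beta-1 study
#'
#' The study's printed table of 18 proteins called as Kpn-beta-1 binding
#' partners in all three cancer cell lines (HeLa, WHCO5, KYSE30) but not in
#' the non-cancer line (hTERT-RPE1).
#'
#' @return Data.frame with columns `group`, `accession`, `protein_name`,
#'   `gene_name`, `molecular_weight_kda`.
#' @seealso [kpnb1_common_core()]
#' @export
kpnb1_cancer_unique <- function() {
  read_candidate_table(system.file("extdata", "kpnb1_cancer_unique.tsv",
                                   package = "apmscall", mustWork = TRUE))
}
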