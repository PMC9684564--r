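# In-code fixtures shared across test files.

# Small protein-group table from a plain intensity matrix.
make_pg <- function(intensity, q = NULL, reverse = NULL, contaminant = NULL,
                    genes = NULL, mw = NULL) {
  ids <- rownames(intensity)
  stopifnot(!is.null(ids), !is.null(colnames(intensity)))
  n <- nrow(intensity)
  records <- data.frame(
    group_id = ids,
    gene_name = if (is.null(genes)) ids else genes,
    q_value = if (is.null(q)) rep(0.001, n) else q,
    is_reverse = if (is.null(reverse)) rep(FALSE, n) else reverse,
    is_contaminant = if (is.null(contaminant)) rep(FALSE, n) else
      contaminant,
    molecular_weight_kda = if (is.null(mw)) rep(NA_real_, n) else mw,
    stringsAsFactors = FALSE
  )
  records$accessions <- as.list(ids)
  protein_group_table(records, intensity)
}

# One condition, n bait + n control replicates.
make_design_1cond <- function(condition = "A", n = 3) {
  sample_design(
    sample_id = c(paste0(condition, "_IP_", seq_len(n)),
                  paste0(condition, "_IgG_", seq_len(n))),
    condition = rep(condition, 2 * n),
    pulldown = rep(c("bait", "control"), each = n),
    replicate = rep(seq_len(n), 2)
  )
}

make_design <- function(conditions, n = 3) {
  parts <- lapply(conditions, make_design_1cond, n = n)
  d <- do.call(rbind, lapply(parts, as.data.frame))
  sample_design(d$sample_id, d$condition, d$pulldown, d$replicate)
}

# Random small instance for property sweeps: <= 12 proteins, random flags,
# q-values straddling the threshold, random detections.
rand_pg_instance <- function(conditions = c("A", "B"), n_reps = 3,
                             n_prot = 12) {
  design <- make_design(conditions, n = n_reps)
  ids <- sprintf("P%02d", seq_len(n_prot))
  det <- matrix(runif(n_prot * nrow(design)) < 0.5, n_prot, nrow(design),
                dimnames = list(ids, design$sample_id))
  intensity <- det * matrix(2^runif(n_prot * nrow(design), 20, 30),
                            n_prot, nrow(design))
  rownames(intensity) <- ids
  table <- make_pg(
    intensity,
    q = sample(c(0.0005, 0.005, 0.01, 0.02), n_prot, replace = TRUE),
    reverse = runif(n_prot) < 0.15,
    contaminant = runif(n_prot) < 0.15
  )
  list(table = table, design = design)
}

# Random condition sets over a small identifier universe.
rand_sets <- function(n_sets = 4, universe_size = 20) {
  universe <- sprintf("id%02d", seq_len(universe_size))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample.int(universe_size, 1)))
  names(sets) <- LETTERS[seq_len(n_sets)]
  sets
}

# MaxQuant-dialect fixture file written from inline text.
write_mq_fixture <- function(path) {
  lines <- c(
    paste("Majority protein IDs", "Gene names", "Q-value", "Reverse",
          "Potential contaminant", "Mol. weight [kDa]",
          "Intensity A1", "Intensity A2", sep = "\t"),
    paste("P62826;Q14974", "RAN", "0.001", "", "", "26.224",
          "1200000", "0", sep = "\t"),
    paste("Q09666", "AHNAK", "0.002", "", "+", "629.1",
          "0", "", sep = "\t"),
    paste("REV_P31946", "", "0.5", "+", "", "", "500", "600", sep = "\t")
  )
  writeLines(lines, path)
  path
}
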