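#!/usr/bin/env Rscript
# Step 2 — call candidate interactors per cell line.
#
# Reads the simulated protein-group table and design from step 1 back
# through the parsers (exercising the full file interface), applies the
# presence/absence classification (q < 0.01, decoy/contaminant removal,
# any-control subtraction, all-of-3 bait replicates) and writes one
# candidate TSV per condition plus a JSON run summary.

suppressPackageStartupMessages(library(apmscall))

in_dir <- "results/sim"
out_dir <- "results/calling"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

table <- read_protein_groups(file.path(in_dir, "proteinGroups.txt"))
design <- read_design(file.path(in_dir, "design.tsv"))
params <- calling_params(q_max = 0.01, min_bait_replicates = "all",
                         control_rule = "any")
cand <- call_candidates(table, design, params)
print(cand)

filtered <- strip_decoys_contaminants(filter_quality(table, params$q_max))
m <- presence_matrix(filtered, design)
for (cond in names(cand$sets)) {
  write_candidate_table(cand$sets[[cond]], table,
                        file.path(out_dir, paste0("candidates_", cond,
                                                  ".tsv")))
  n_ctrl <- length(control_detected(m, design, cond, "all"))
  message(sprintf("%s: %d candidates; %d proteins in all %d controls",
                  cond, length(cand$sets[[cond]]), n_ctrl,
                  sum(design$condition == cond &
                        design$pulldown == "control")))
}

jsonlite::write_json(
  list(params = unclass(params),
       n_input_groups = n_groups(table),
       n_after_filters = n_groups(filtered),
       candidates = lapply(cand$sets, length),
       input_md5 = unname(tools::md5sum(file.path(in_dir,
                                                  "proteinGroups.txt")))),
  file.path(out_dir, "run_summary.json"), auto_unbox = TRUE)
message("wrote ", out_dir)
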