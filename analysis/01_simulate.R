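#!/usr/bin/env Rscript
# Step 1 — generate the synthetic AP-MS experiment.
#
# World: 4 cell lines (1 non-cancer + 3 cancer) x {bait IP, IgG control} x 3
# replicates; planted truth = 1 bait, 38 common interactors, 18
# cancer-unique interactors, 100 nonspecific binders, 10 contaminants,
# 10 decoys. Writes a MaxQuant-style protein-group table, the sample design
# and the planted labels under results/sim/.

suppressPackageStartupMessages(library(apmscall))

out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260918L

params <- paper_like_params(seed = seed)
truth <- generate_truth(params)
sim <- simulate_protein_groups(truth, params)

write_protein_groups(sim$table, file.path(out_dir, "proteinGroups.txt"))
write_design(sim$design, file.path(out_dir, "design.tsv"))
jsonlite::write_json(
  list(seed = seed, label = as.list(truth$label),
       group_membership = truth$group_membership),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE)

print(sim$table)
message("bait detected in every bait IP: ",
        all(sim$table$intensity[truth$bait_id,
                                sim$design$sample_id[
                                  sim$design$pulldown == "bait"]] > 0))
message("wrote ", out_dir, "/{proteinGroups.txt, design.tsv, truth.json}")
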