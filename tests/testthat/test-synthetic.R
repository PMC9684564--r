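test_that("generate_truth plants disjoint classes with requested sizes", {
  p <- sim_params(seed = 1L)
  tr <- generate_truth(p)
  expect_identical(sum(tr$label == "true_common"), 38L)
  expect_identical(sum(tr$label == "true_group:cancer"), 18L)
  expect_identical(sum(tr$label == "bait"), 1L)
  expect_identical(sum(tr$label == "background"), 100L)
  # labels partition identifiers
  expect_false(anyDuplicated(names(tr$label)) > 0)

  tr2 <- generate_truth(sim_params(seed = 1L))
  expect_identical(tr, tr2)  # same seed, same truth

  p0 <- sim_params(n_common_interactors = 0, seed = 2L)
  expect_identical(sum(generate_truth(p0)$label == "true_common"), 0L)
})

test_that("sim_params validates probabilities, counts and groups", {
  expect_error(sim_params(p_det_true = 1.2), "p_det_true")
  expect_error(sim_params(n_background = -1), "non-negative")
  expect_error(sim_params(group_membership = list(cancer = "NotACondition")),
               "unknown condition")
  expect_error(sim_params(n_unique_interactors = list(other = 5)),
               "same groups")
  expect_error(sim_params(seed = 2^31), "seed")
})

test_that("simulated tables honor the detection rules and flags", {
  p <- sim_params(n_decoys = 5, seed = 4L)
  tr <- generate_truth(p)
  sim <- simulate_protein_groups(tr, p)
  expect_identical(sum(sim$table$records$is_reverse), 5L)
  expect_identical(sum(sim$table$records$is_contaminant), 10L)

  bait_s <- sim$design$sample_id[sim$design$pulldown == "bait"]
  ctrl_s <- sim$design$sample_id[sim$design$pulldown == "control"]
  bait_row <- sim$table$intensity[tr$bait_id, ]
  expect_true(all(bait_row[bait_s] > 0))   # bait in every bait IP
  expect_true(all(bait_row[ctrl_s] == 0))  # and in no control

  # true interactors never appear in controls
  true_ids <- names(tr$label)[tr$label %in% c("true_common",
                                              "true_group:cancer")]
  expect_true(all(sim$table$intensity[true_ids, ctrl_s] == 0))

  # group-unique interactors never appear outside their group's conditions
  uniq <- names(tr$label)[tr$label == "true_group:cancer"]
  rpe_bait <- sim$design$sample_id[sim$design$condition == "hTERT_RPE1" &
                                     sim$design$pulldown == "bait"]
  expect_true(all(sim$table$intensity[uniq, rpe_bait] == 0))

  # q-values: real classes under the filter, junk rows above q_junk_min
  junk <- sim$table$records$is_reverse | sim$table$records$is_contaminant
  expect_true(all(sim$table$records$q_value[!junk] < p$q_true_max))
  expect_true(all(sim$table$records$q_value[junk] >= p$q_junk_min))
})

test_that("same seed gives byte-identical output; parsing is total", {
  p <- sim_params(seed = 9L)
  tr <- generate_truth(p)
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_protein_groups(simulate_protein_groups(tr, p)$table, f1)
  write_protein_groups(simulate_protein_groups(tr, p)$table, f2)
  expect_identical(readLines(f1), readLines(f2))

  # the generator's output parses with zero row errors and round-trips
  tab <- read_protein_groups(f1)
  sim <- simulate_protein_groups(tr, p)
  expect_identical(tab$sample_ids, sim$table$sample_ids)
  expect_identical(tab$records$group_id, sim$table$records$group_id)
  expect_identical(tab$records$is_reverse, sim$table$records$is_reverse)
  expect_equal(unname(tab$intensity), unname(sim$table$intensity),
               tolerance = 1e-12)
  expect_equal(tab$records$q_value, sim$table$records$q_value,
               tolerance = 1e-12)
})

test_that("forced detection worlds behave exactly as constructed", {
  # p_det_true = 1 and p_det_bg_ctrl = 1: background fully subtracted,
  # candidates = bait + planted interactors per condition, exactly
  p <- noiseless_params(seed = 5L)
  tr <- generate_truth(p)
  sim <- simulate_protein_groups(tr, p)
  cand <- call_candidates(sim$table, sim$design)
  for (cond in p$conditions)
    expect_setequal(cand$sets[[cond]], planted_positives(tr, cond))

  rec <- evaluate_recovery(cand, compare_conditions(cand), tr)
  expect_true(all(rec$per_condition$precision == 1))
  expect_true(all(rec$per_condition$recall == 1))
  expect_equal(rec$common_core_recovery, 1)
  expect_equal(unname(rec$unique_recovery["cancer"]), 1)
  expect_identical(nrow(rec$false_positives), 0L)

  # p_det_bg_ctrl = 0, p_det_bg_bait = 1: every background binder becomes a
  # false positive, and every false positive is labeled background
  p2 <- sim_params(p_det_true = 1, p_det_bg_bait = 1, p_det_bg_ctrl = 0,
                   n_contaminants = 0, n_decoys = 0, seed = 6L)
  tr2 <- generate_truth(p2)
  sim2 <- simulate_protein_groups(tr2, p2)
  cand2 <- call_candidates(sim2$table, sim2$design)
  rec2 <- evaluate_recovery(cand2, compare_conditions(cand2), tr2)
  expect_true(all(rec2$per_condition$precision < 1))
  expect_true(all(rec2$false_positives$label == "background"))
  expect_identical(sort(unique(rec2$false_positives$identifier)),
                   sort(names(tr2$label)[tr2$label == "background"]))
})

test_that("expected_recall and expected_background_fp_rate close forms", {
  expect_equal(expected_recall(1, 3), 1)
  expect_equal(expected_recall(0.6, 3), 0.216)
  expect_equal(expected_recall(0.5, 3), 0.125)
  expect_error(expected_recall(1.1, 3), "p_det")
  expect_equal(expected_background_fp_rate(0.8, 0.5, 3),
               0.8^3 * 0.5^3)
})

test_that("empirical background FP rate matches its closed form", {
  p_bait <- 0.8; p_ctrl <- 0.5
  fp <- 0L; trials <- 0L
  for (seed in 1:8) {
    p <- sim_params(conditions = c("A", "B"), n_common_interactors = 5,
                    n_unique_interactors = list(), group_membership = list(),
                    n_background = 200, n_contaminants = 0, n_decoys = 0,
                    p_det_true = 1, p_det_bg_bait = p_bait,
                    p_det_bg_ctrl = p_ctrl, seed = seed)
    tr <- generate_truth(p)
    sim <- simulate_protein_groups(tr, p)
    cand <- call_candidates(sim$table, sim$design)
    bg <- names(tr$label)[tr$label == "background"]
    for (cond in p$conditions) {
      fp <- fp + length(intersect(cand$sets[[cond]], bg))
      trials <- trials + length(bg)
    }
  }
  want <- expected_background_fp_rate(p_bait, p_ctrl, 3)
  se <- sqrt(want * (1 - want) / trials)
  expect_lt(abs(fp / trials - want), 3 * se)
})

test_that("structure recovery is exact when detection is certain", {
  p <- noiseless_params(seed = 7L)
  tr <- generate_truth(p)
  sim <- simulate_protein_groups(tr, p)
  cmp <- compare_conditions(call_candidates(sim$table, sim$design))
  planted_common <- names(tr$label)[tr$label == "true_common"]
  expect_setequal(cmp$common_all, c(tr$bait_id, planted_common))
  expect_setequal(unique_to(cmp, p$group_membership$cancer),
                  names(tr$label)[tr$label == "true_group:cancer"])
})

test_that("evaluate_recovery rejects foreign identifier namespaces", {
  p <- noiseless_params(seed = 8L)
  tr <- generate_truth(p)
  cand <- structure(list(sets = list(hTERT_RPE1 = "NOT_AN_ID"),
                         params = calling_params()),
                    class = "candidate_sets")
  expect_error(evaluate_recovery(cand, NULL, tr), "namespace")
})
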