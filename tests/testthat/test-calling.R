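test_that("filter_quality keeps q strictly below the threshold", {
  intensity <- matrix(1, 3, 2, dimnames = list(c("P1", "P2", "P3"),
                                               c("s1", "s2")))
  tab <- make_pg(intensity, q = c(0.001, 0.01, 0.5))
  kept <- filter_quality(tab, 0.01)
  expect_identical(kept$records$group_id, "P1")  # 0.01 boundary excluded
  expect_identical(n_groups(filter_quality(tab, 1)), 3L)
  empty <- filter_quality(make_pg(intensity, q = rep(0.5, 3)), 0.01)
  expect_identical(n_groups(empty), 0L)
  expect_error(filter_quality(tab, 0), "q_max")
})

test_that("strip_decoys_contaminants removes flagged rows only", {
  intensity <- matrix(1, 3, 1, dimnames = list(c("P1", "REV_X", "KRT1"),
                                               "s1"))
  tab <- make_pg(intensity, reverse = c(FALSE, TRUE, FALSE),
                 contaminant = c(FALSE, FALSE, TRUE))
  expect_identical(strip_decoys_contaminants(tab)$records$group_id, "P1")
})

test_that("presence_matrix matches a hand-computed truth table", {
  design <- sample_design(c("s1", "s2"), c("A", "A"), c("bait", "control"),
                          c(1, 1))
  intensity <- matrix(c(0, 1e7, 3.5, 0), 2, 2, byrow = TRUE,
                      dimnames = list(c("P1", "P2"), c("s1", "s2")))
  m <- presence_matrix(make_pg(intensity), design)
  expect_identical(m, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
                             byrow = TRUE,
                             dimnames = list(c("P1", "P2"),
                                             c("s1", "s2"))))
  d2 <- sample_design(c("s1", "s9"), c("A", "A"), c("bait", "control"),
                      c(1, 1))
  expect_error(presence_matrix(make_pg(intensity), d2), "s9")
})

test_that("control_detected implements the any/all control rules", {
  design <- make_design_1cond("A", 3)
  intensity <- matrix(0, 2, 6,
                      dimnames = list(c("once", "never"),
                                      design$sample_id))
  intensity["once", "A_IgG_2"] <- 100   # 1 of 3 controls
  m <- presence_matrix(make_pg(intensity), design)
  expect_identical(control_detected(m, design, "A", "any"), "once")
  expect_identical(control_detected(m, design, "A", "all"), character(0))

  d_noctrl <- sample_design("x", "B", "bait", 1)
  expect_error(control_detected(m[, 1, drop = FALSE], d_noctrl, "B"),
               "no control samples")
})

test_that("replicate_consistent implements the all / at-least-k rules", {
  design <- make_design_1cond("A", 3)
  intensity <- matrix(0, 2, 6,
                      dimnames = list(c("full", "two"), design$sample_id))
  intensity["full", c("A_IP_1", "A_IP_2", "A_IP_3")] <- 1
  intensity["two", c("A_IP_1", "A_IP_3")] <- 1
  m <- presence_matrix(make_pg(intensity), design)
  expect_identical(replicate_consistent(m, design, "A", "all"), "full")
  expect_setequal(replicate_consistent(m, design, "A", 2), c("full", "two"))
  expect_error(replicate_consistent(m, design, "A", 4), "exceeds")
})

test_that("call_candidates applies the three rules jointly (hand trace)", {
  design <- make_design_1cond("A", 3)
  bait_s <- design$sample_id[design$pulldown == "bait"]
  ctrl_s <- design$sample_id[design$pulldown == "control"]
  intensity <- matrix(0, 4, 6,
                      dimnames = list(c("bait", "interactor", "sticky",
                                        "dropout"), design$sample_id))
  intensity["bait", bait_s] <- 1e8
  intensity["interactor", bait_s] <- 1e6
  intensity["sticky", c(bait_s, ctrl_s[1:2])] <- 1e5
  intensity["dropout", bait_s[1:2]] <- 1e6
  cand <- call_candidates(make_pg(intensity), design)
  expect_setequal(cand$sets$A, c("bait", "interactor"))

  # everything seen in controls -> empty candidate set
  intensity2 <- intensity
  intensity2[, ctrl_s[1]] <- 1
  cand2 <- call_candidates(make_pg(intensity2), design)
  expect_length(cand2$sets$A, 0)
})

test_that("quality/decoy filters precede binarization (no control masking)", {
  # a decoy detected in a control must not subtract a real protein with the
  # same detection pattern
  design <- make_design_1cond("A", 2)
  intensity <- matrix(0, 2, 4,
                      dimnames = list(c("real", "REV_real"),
                                      design$sample_id))
  intensity["real", c("A_IP_1", "A_IP_2")] <- 10
  intensity["REV_real", ] <- 10  # decoy everywhere, incl. controls
  tab <- make_pg(intensity, reverse = c(FALSE, TRUE))
  cand <- call_candidates(tab, design)
  expect_identical(cand$sets$A, "real")
})

test_that("call_candidates equals the brute-force oracle on random instances", {
  set.seed(42)
  for (i in 1:40) {
    inst <- rand_pg_instance(conditions = c("A", "B"), n_reps = 3,
                             n_prot = sample(3:12, 1))
    q_max <- sample(c(0.01, 0.02), 1)
    control_rule <- sample(c("any", "all"), 1)
    min_reps <- sample(list("all", 2L), 1)[[1]]
    got <- call_candidates(inst$table, inst$design,
                           calling_params(q_max = q_max,
                                          min_bait_replicates = min_reps,
                                          control_rule = control_rule))
    want <- brute_candidates(inst$table, inst$design, q_max = q_max,
                             min_reps = min_reps,
                             control_rule = control_rule)
    for (cond in names(want))
      expect_identical(got$sets[[cond]], want[[cond]])
  }
})

test_that("candidate sets are monotone in q_max and min_reps", {
  set.seed(7)
  for (i in 1:10) {
    inst <- rand_pg_instance(n_prot = 12)
    loose <- call_candidates(inst$table, inst$design,
                             calling_params(q_max = 0.05))
    tight <- call_candidates(inst$table, inst$design,
                             calling_params(q_max = 0.005))
    for (cond in names(loose$sets))
      expect_true(all(tight$sets[[cond]] %in% loose$sets[[cond]]))

    all3 <- call_candidates(inst$table, inst$design,
                            calling_params(min_bait_replicates = "all"))
    k2 <- call_candidates(inst$table, inst$design,
                          calling_params(min_bait_replicates = 2))
    for (cond in names(all3$sets))
      expect_true(all(all3$sets[[cond]] %in% k2$sets[[cond]]))
  }
})

test_that("candidates are disjoint from control-detected proteins", {
  set.seed(11)
  for (i in 1:10) {
    inst <- rand_pg_instance(n_prot = 10)
    for (rule in c("any", "all")) {
      cand <- call_candidates(inst$table, inst$design,
                              calling_params(control_rule = rule))
      filtered <- strip_decoys_contaminants(
        filter_quality(inst$table, 0.01))
      m <- presence_matrix(filtered, inst$design)
      for (cond in names(cand$sets)) {
        ctrl <- control_detected(m, inst$design, cond, rule)
        expect_length(intersect(cand$sets[[cond]], ctrl), 0)
      }
    }
  }
})

test_that("calling is invariant to record and sample-column order", {
  set.seed(13)
  inst <- rand_pg_instance(n_prot = 12)
  cand <- call_candidates(inst$table, inst$design)

  perm_r <- sample(n_groups(inst$table))
  perm_c <- sample(length(inst$table$sample_ids))
  records <- inst$table$records[perm_r, , drop = FALSE]
  rownames(records) <- NULL
  shuffled <- protein_group_table(
    records, inst$table$intensity[perm_r, perm_c, drop = FALSE])
  cand2 <- call_candidates(shuffled, inst$design)
  expect_identical(cand$sets, cand2$sets)
})
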