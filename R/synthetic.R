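#' Parameters for the synthetic AP-MS generator
#'
#' Describes a pull-down experiment with planted ground truth: one bait
#' protein present in every bait IP, a common-interactor set planted in all
#' conditions, group-specific interactor sets, nonspecific ("sticky")
#' background binders seen in both pull-down types, plus flagged contaminant
#' and decoy rows. Detected log2 intensities follow
#' `protein mean + shared sample effect + residual noise`, with a larger
#' residual for nonspecific binders so that isotype-control replicates are
#' less concordant than bait replicates, as observed in real IP-MS QC.
#'
#' Defaults encode a paper-like study design: 4 cell lines (one non-cancer,
#' three cancer) x \{bait IP, IgG control\} x 3 replicates, 38 planted common
#' interactors and 18 planted cancer-group-unique interactors.
#'
#' @param conditions Condition (cell line) labels.
#' @param n_replicates Replicates per (condition, pulldown). Default 3.
#' @param n_common_interactors True interactors planted in every condition.
#' @param n_unique_interactors Named list: group label -> count of true
#'   interactors planted only in that group's conditions.
#' @param group_membership Named list: group label -> condition labels.
#' @param n_background Nonspecific binders (detected in bait and control
#'   samples alike).
#' @param n_contaminants Rows flagged as common contaminants.
#' @param n_decoys Rows flagged as reverse (decoy) hits.
#' @param p_det_true Per-bait-replicate detection probability of a true
#'   interactor (independent across samples).
#' @param p_det_bg_bait,p_det_bg_ctrl Detection probability of a background
#'   binder in bait and in control samples.
#' @param mu_log2 Mean log2 intensity of a protein.
#' @param sigma_protein SD of protein mean log2 intensities (between-protein
#'   abundance spread; dominates replicate correlation).
#' @param sigma_sample SD of the shared per-sample effect (loading shift).
#' @param sigma_noise Residual SD of a detected specific-interactor
#'   measurement.
#' @param sigma_noise_background Residual SD for nonspecific binders,
#'   contaminants and decoys (larger: stochastic bead/antibody binding).
#' @param q_true_max Planted real identifications draw q-values uniformly
#'   below this (default 0.009, i.e. under the 0.01 quality filter).
#' @param q_junk_min Contaminant/decoy rows draw q-values uniformly above
#'   this (default 0.05).
#' @param seed Integer seed in \[0, 2^31 - 2\]; [generate_truth()] uses
#'   `seed`, [simulate_protein_groups()] uses `seed + 1`.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(conditions = c("hTERT_RPE1", "HeLa", "WHCO5",
                                      "KYSE30"),
                       n_replicates = 3,
                       n_common_interactors = 38,
                       n_unique_interactors = list(cancer = 18),
                       group_membership = list(cancer = c("HeLa", "WHCO5",
                                                          "KYSE30")),
                       n_background = 100,
                       n_contaminants = 10,
                       n_decoys = 10,
                       p_det_true = 0.9,
                       p_det_bg_bait = 0.4,
                       p_det_bg_ctrl = 0.8,
                       mu_log2 = 25,
                       sigma_protein = 4,
                       sigma_sample = 0.3,
                       sigma_noise = 0.25,
                       sigma_noise_background = 1.0,
                       q_true_max = 0.009,
                       q_junk_min = 0.05,
                       seed = 1L) {
  stopifnot(length(conditions) >= 1, !anyDuplicated(conditions))
  probs <- c(p_det_true = p_det_true, p_det_bg_bait = p_det_bg_bait,
             p_det_bg_ctrl = p_det_bg_ctrl)
  if (any(probs < 0 | probs > 1))
    stop("detection probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  counts <- c(n_replicates = n_replicates,
              n_common_interactors = n_common_interactors,
              n_background = n_background,
              n_contaminants = n_contaminants, n_decoys = n_decoys)
  if (any(counts < 0) || n_replicates < 1)
    stop("counts must be non-negative (and n_replicates >= 1)")
  sigmas <- c(sigma_protein, sigma_sample, sigma_noise,
              sigma_noise_background)
  if (any(sigmas < 0)) stop("sigma values must be >= 0")
  if (!setequal(names(n_unique_interactors), names(group_membership)))
    stop("n_unique_interactors and group_membership must name the same groups")
  for (g in names(group_membership)) {
    bad <- setdiff(group_membership[[g]], conditions)
    if (length(bad) > 0)
      stop("group '", g, "' names unknown condition(s): ",
           paste(bad, collapse = ", "))
  }
  if (q_true_max <= 0 || q_true_max > 1 || q_junk_min < 0 || q_junk_min >= 1)
    stop("q_true_max must be in (0, 1] and q_junk_min in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed < 0 || seed > .Machine$integer.max - 1)
    stop("seed must be an integer in [0, 2^31 - 2]")
  seed <- as.integer(seed)
  structure(
    list(conditions = conditions, n_replicates = as.integer(n_replicates),
         n_common_interactors = as.integer(n_common_interactors),
         n_unique_interactors = lapply(n_unique_interactors, as.integer),
         group_membership = group_membership,
         n_background = as.integer(n_background),
         n_contaminants = as.integer(n_contaminants),
         n_decoys = as.integer(n_decoys),
         p_det_true = p_det_true, p_det_bg_bait = p_det_bg_bait,
         p_det_bg_ctrl = p_det_bg_ctrl,
         mu_log2 = mu_log2, sigma_protein = sigma_protein,
         sigma_sample = sigma_sample, sigma_noise = sigma_noise,
         sigma_noise_background = sigma_noise_background,
         q_true_max = q_true_max, q_junk_min = q_junk_min, seed = seed),
    class = "sim_params"
  )
}

#' Paper-like preset of the synthetic generator
#'
#' The default world of [sim_params()]: 4 cell lines (one non-cancer, three
#' cancer), biological triplicates with IgG isotype-control triplicates, 38
#' planted common-core and 18 planted cancer-unique interactors.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [sim_params()].
#' @return A `sim_params`.
#' @export
paper_like_params <- function(seed = 1L, ...) sim_params(seed = seed, ...)

#' Noiseless preset of the synthetic generator
#'
#' Every planted interactor is detected in every bait replicate of its
#' conditions and every background binder in every sample of both pull-down
#' types, so candidate calling must recover exactly the bait plus the planted
#' interactor sets (background binders are fully subtracted by the controls).
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [sim_params()].
#' @return A `sim_params`.
#' @export
noiseless_params <- function(seed = 1L, ...) {
  sim_params(p_det_true = 1, p_det_bg_bait = 1, p_det_bg_ctrl = 1,
             seed = seed, ...)
}

#' Generate planted ground-truth labels
#'
#' Deterministic for a fixed seed. Classes are disjoint: one bait,
#' `n_common_interactors` common interactors (planted in every condition),
#' per-group unique interactors (planted only in the group's conditions),
#' background binders, contaminants and decoys.
#'
#' @param params A `sim_params`.
#' @return An object of class `"synthetic_truth"`: list with `label` (named
#'   character: identifier -> one of `"bait"`, `"true_common"`,
#'   `"true_group:<group>"`, `"background"`, `"contaminant"`, `"decoy"`),
#'   `bait_id`, `group_membership`, `conditions` and `params`.
#' @export
generate_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  pad <- function(prefix, n) if (n == 0) character(0) else
    sprintf("%s_%03d", prefix, seq_len(n))
  label <- stats::setNames("bait", "BAIT001")
  common <- pad("COMMON", params$n_common_interactors)
  label <- c(label, stats::setNames(rep("true_common", length(common)),
                                    common))
  for (g in names(params$n_unique_interactors)) {
    u <- pad(paste0("UNIQ", toupper(g)), params$n_unique_interactors[[g]])
    label <- c(label, stats::setNames(rep(paste0("true_group:", g),
                                          length(u)), u))
  }
  bg <- pad("BG", params$n_background)
  label <- c(label, stats::setNames(rep("background", length(bg)), bg))
  cont <- pad("CONT", params$n_contaminants)
  label <- c(label, stats::setNames(rep("contaminant", length(cont)), cont))
  dec <- pad("REV", params$n_decoys)
  label <- c(label, stats::setNames(rep("decoy", length(dec)), dec))
  structure(
    list(label = label, bait_id = "BAIT001",
         group_membership = params$group_membership,
         conditions = params$conditions, params = params),
    class = "synthetic_truth"
  )
}

#' True-interactor identifiers planted for one condition
#'
#' Bait + common interactors + the unique interactors of every group the
#' condition belongs to: the positives that candidate calling should recover
#' in that condition.
#'
#' @param truth A `synthetic_truth`.
#' @param condition Condition label.
#' @return Character vector of identifiers.
#' @export
planted_positives <- function(truth, condition) {
  if (!condition %in% truth$conditions)
    stop("unknown condition: ", condition)
  lab <- truth$label
  pos <- names(lab)[lab %in% c("bait", "true_common")]
  for (g in names(truth$group_membership)) {
    if (condition %in% truth$group_membership[[g]])
      pos <- c(pos, names(lab)[lab == paste0("true_group:", g)])
  }
  pos
}

#' Simulate a protein-group table and its sample design
#'
#' Applies the detection model to the planted truth: the bait is present
#' (intensity > 0) in every bait sample and absent from controls; true
#' interactors are present in each bait replicate of their conditions
#' independently with `p_det_true` and absent from controls; background
#' binders (and contaminant/decoy rows) are present with `p_det_bg_bait` in
#' bait samples and `p_det_bg_ctrl` in controls. Detected cells get intensity
#' `2^(protein mean + sample effect + Normal(0, sigma))` with the residual
#' `sigma_noise` for specific classes and `sigma_noise_background` for
#' nonspecific rows; undetected cells are written as 0. q-values are drawn
#' below `q_true_max` for real classes and above `q_junk_min` for
#' contaminant/decoy rows. The output is byte-identical across runs with the
#' same seed and parses through [read_protein_groups()] with zero row errors.
#'
#' @param truth A `synthetic_truth` from [generate_truth()].
#' @param params The same `sim_params` used for the truth.
#' @return List with `table` (a `protein_group_table`) and `design` (a
#'   `sample_design`; samples named `<condition>_IP_<r>` and
#'   `<condition>_IgG_<r>`).
#' @export
simulate_protein_groups <- function(truth, params) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  conds <- params$conditions
  reps <- seq_len(params$n_replicates)
  design <- sample_design(
    sample_id = c(t(outer(conds, reps, function(cn, r)
      paste0(cn, "_IP_", r))),
      t(outer(conds, reps, function(cn, r) paste0(cn, "_IgG_", r)))),
    condition = c(rep(conds, each = length(reps)),
                  rep(conds, each = length(reps))),
    pulldown = rep(c("bait", "control"),
                   each = length(conds) * length(reps)),
    replicate = rep(reps, times = 2 * length(conds))
  )
  ids <- names(truth$label)
  lab <- truth$label
  n_prot <- length(ids)
  n_samp <- nrow(design)

  bait_cols <- design$pulldown == "bait"
  cond_of <- design$condition

  # detection
  det <- matrix(FALSE, n_prot, n_samp,
                dimnames = list(ids, design$sample_id))
  specific <- lab %in% c("bait", "true_common") |
    startsWith(lab, "true_group:")
  for (i in seq_len(n_prot)) {
    li <- lab[i]
    if (li == "bait") {
      det[i, bait_cols] <- TRUE
    } else if (li == "true_common" || startsWith(li, "true_group:")) {
      eligible <- bait_cols
      if (startsWith(li, "true_group:")) {
        g <- sub("^true_group:", "", li)
        eligible <- eligible & cond_of %in% truth$group_membership[[g]]
      }
      det[i, eligible] <- stats::runif(sum(eligible)) < params$p_det_true
    } else { # background, contaminant, decoy
      det[i, bait_cols] <- stats::runif(sum(bait_cols)) <
        params$p_det_bg_bait
      det[i, !bait_cols] <- stats::runif(sum(!bait_cols)) <
        params$p_det_bg_ctrl
    }
  }

  # intensities: protein mean + shared sample effect + residual
  prot_mean <- stats::rnorm(n_prot, params$mu_log2, params$sigma_protein)
  prot_mean[lab == "bait"] <- params$mu_log2 + 3 * params$sigma_protein / 2
  samp_eff <- stats::rnorm(n_samp, 0, params$sigma_sample)
  resid_sd <- ifelse(specific, params$sigma_noise,
                     params$sigma_noise_background)
  intensity <- matrix(0, n_prot, n_samp,
                      dimnames = list(NULL, design$sample_id))
  for (i in seq_len(n_prot)) {
    s <- which(det[i, ])
    if (length(s) > 0)
      intensity[i, s] <- 2^(prot_mean[i] + samp_eff[s] +
                              stats::rnorm(length(s), 0, resid_sd[i]))
  }

  q <- ifelse(lab %in% c("contaminant", "decoy"),
              stats::runif(n_prot, params$q_junk_min, 1),
              stats::runif(n_prot, 0, params$q_true_max))
  records <- data.frame(
    group_id = ids,
    gene_name = ids,
    q_value = q,
    is_reverse = lab == "decoy",
    is_contaminant = lab == "contaminant",
    molecular_weight_kda = round(stats::runif(n_prot, 10, 300), 3),
    stringsAsFactors = FALSE
  )
  records$accessions <- as.list(ids)
  list(table = protein_group_table(records, intensity), design = design)
}

#' Closed-form recall of the all-replicates rule
#'
#' With independent per-replicate detection probability `p_det`, the
#' probability that a true interactor is detected in all `n_reps` bait
#' replicates (and hence called under the all-replicates rule) is
#' `p_det ^ n_reps`.
#'
#' @param p_det Detection probability in \[0, 1\].
#' @param n_reps Number of bait replicates (>= 1).
#' @return `p_det ^ n_reps`.
#' @export
#' @examples
#' expected_recall(0.6, 3) # 0.216
expected_recall <- function(p_det, n_reps) {
  if (any(p_det < 0 | p_det > 1)) stop("p_det must lie in [0, 1]")
  if (any(n_reps < 1)) stop("n_reps must be >= 1")
  p_det^n_reps
}

#' Closed-form false-positive rate for background binders
#'
#' Under the all-replicates bait rule and the any-replicate control rule, a
#' background binder becomes a false positive iff it is detected in all
#' `n_reps` bait replicates and in no control replicate:
#' `p_bait^n_reps * (1 - p_ctrl)^n_reps`.
#'
#' @param p_bait,p_ctrl Detection probabilities in bait / control samples.
#' @param n_reps Replicates per pull-down type.
#' @return The false-positive probability.
#' @export
expected_background_fp_rate <- function(p_bait, p_ctrl, n_reps) {
  if (any(c(p_bait, p_ctrl) < 0 | c(p_bait, p_ctrl) > 1))
    stop("probabilities must lie in [0, 1]")
  p_bait^n_reps * (1 - p_ctrl)^n_reps
}

#' Evaluate recovery of the planted truth
#'
#' Scores called candidate sets (and their cross-condition comparison)
#' against the planted labels: per-condition precision / recall / F1 against
#' bait + planted interactors, the fraction of planted common interactors
#' recovered in the all-condition common core, the fraction of each planted
#' group-unique set recovered in the corresponding group-unique call, and the
#' identities (with labels) of all false positives.
#'
#' @param candidates A `candidate_sets` from [call_candidates()].
#' @param comparison A `comparison_result` over the same sets (may be `NULL`
#'   when fewer than 2 conditions were called; structure metrics are then
#'   skipped).
#' @param truth The `synthetic_truth` the data were simulated from.
#' @return List of class `"recovery_metrics"` with `per_condition`
#'   (data.frame: condition, n_called, n_true, tp, precision, recall, f1),
#'   `common_core_recovery`, `unique_recovery` (named per group),
#'   `false_positives` (data.frame: condition, identifier, label).
#' @export
evaluate_recovery <- function(candidates, comparison, truth) {
  stopifnot(inherits(candidates, "candidate_sets"),
            inherits(truth, "synthetic_truth"))
  known <- names(truth$label)
  rows <- list(); fps <- list()
  for (cond in names(candidates$sets)) {
    called <- candidates$sets[[cond]]
    alien <- setdiff(called, known)
    if (length(alien) > 0)
      stop("identifier namespace mismatch; called identifiers not in ",
           "truth: ", paste(utils::head(alien, 5), collapse = ", "))
    pos <- planted_positives(truth, cond)
    tp <- length(intersect(called, pos))
    precision <- if (length(called) == 0) NA_real_ else tp / length(called)
    recall <- tp / length(pos)
    f1 <- if (is.na(precision) || precision + recall == 0) NA_real_ else
      2 * precision * recall / (precision + recall)
    rows[[cond]] <- data.frame(
      condition = cond, n_called = length(called), n_true = length(pos),
      tp = tp, precision = precision, recall = recall, f1 = f1,
      stringsAsFactors = FALSE)
    fp <- setdiff(called, pos)
    if (length(fp) > 0)
      fps[[cond]] <- data.frame(condition = cond, identifier = fp,
                                label = unname(truth$label[fp]),
                                stringsAsFactors = FALSE)
  }
  per_condition <- do.call(rbind, unname(rows))
  false_positives <- if (length(fps) > 0) do.call(rbind, unname(fps)) else
    data.frame(condition = character(0), identifier = character(0),
               label = character(0), stringsAsFactors = FALSE)

  common_recovery <- NA_real_
  unique_recovery <- stats::setNames(numeric(0), character(0))
  if (!is.null(comparison)) {
    stopifnot(inherits(comparison, "comparison_result"))
    planted_common <- names(truth$label)[truth$label == "true_common"]
    common_recovery <- if (length(planted_common) == 0) NA_real_ else
      length(intersect(planted_common, comparison$common_all)) /
        length(planted_common)
    for (g in names(truth$group_membership)) {
      planted_g <- names(truth$label)[truth$label ==
                                        paste0("true_group:", g)]
      if (length(planted_g) == 0) next
      got <- unique_to(comparison, truth$group_membership[[g]])
      unique_recovery[g] <- length(intersect(planted_g, got)) /
        length(planted_g)
    }
  }
  structure(
    list(per_condition = per_condition,
         common_core_recovery = common_recovery,
         unique_recovery = unique_recovery,
         false_positives = false_positives),
    class = "recovery_metrics"
  )
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("recovery vs planted truth:\n")
  pc <- x$per_condition
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %s: precision %.3f, recall %.3f (called %d / true %d)\n",
                pc$condition[i], pc$precision[i], pc$recall[i],
                pc$n_called[i], pc$n_true[i]))
  if (!is.na(x$common_core_recovery))
    cat(sprintf("  common-core recovery: %.3f\n", x$common_core_recovery))
  for (g in names(x$unique_recovery))
    cat(sprintf("  unique-set recovery (%s): %.3f\n", g,
                x$unique_recovery[[g]]))
  cat(sprintf("  false positives: %d\n", nrow(x$false_positives)))
  invisible(x)
}
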