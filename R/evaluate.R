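#' Run the full privacy/utility evaluation pipeline
#'
#' For each trial: sample case/control/test cohorts from the scenario's
#' population model, anonymize the case and control tables (each at the full
#' budget — the groups are disjoint, so parallel composition applies),
#' score significant-SNP recovery across the p-value cutoffs, and estimate
#' the membership-attack power on the case group at the given false-positive
#' rate (population frequencies from the test group, pool frequencies
#' recovered from the case release).  Results are averaged over trials.
#'
#' @param scenario scenario name for [challenge_scenario()], or a list as
#'   returned by it.
#' @param epsilon privacy budget (scalar or vector; one result section per
#'   value).
#' @param h number of specializations per release.
#' @param block_size SNPs per block.
#' @param trials number of Monte-Carlo trials to average over.
#' @param cutoffs p-value cutoffs for the utility report.
#' @param fpr false-positive rate for attack power.
#' @param attack_mode binarization mode, see [binarize()].
#' @param taxonomy_style `"prefix"` (default; multilevel low-branching trees,
#'   see [build_prefix_taxonomy()]) or `"flat"` (two-level trees; only
#'   practical for small panels, since one specialization of a flat tree
#'   multiplies the partition count by the full observed-value count).
#' @param rounding released-count mode, see [anonymize()].
#' @param seed master seed; every random stream of the run derives from it.
#' @return An `evaluation_report`: list with `config` (fully resolved,
#'   including the model digest), `utility` (per epsilon: mean metrics per
#'   cutoff), `attack` (per epsilon: mean power), and `per_trial` data.
#' @export
run_evaluate <- function(scenario = "chr2_like", epsilon = 1, h = 5L,
                         block_size = 6L, trials = 100L,
                         cutoffs = c(5e-2, 1e-2, 1e-3, 1e-5), fpr = 0.05,
                         attack_mode = "per_allele",
                         taxonomy_style = c("prefix", "flat"),
                         rounding = "raw", seed = 1L) {
  taxonomy_style <- match.arg(taxonomy_style)
  if (is.character(scenario)) scenario <- challenge_scenario(scenario)
  model <- scenario$model
  n <- scenario$n_per_group
  build_tax <- switch(taxonomy_style, prefix = build_prefix_taxonomy,
                      flat = build_flat_taxonomy)
  blocks <- make_blocks(model$m, block_size)
  trial_seeds <- derive_seeds(seed, trials)
  utility_rows <- list(); power_rows <- list()
  for (eps in epsilon) {
    for (t in seq_len(trials)) {
      s <- derive_seeds(trial_seeds[t], 6)
      case <- sample_cohort(model, n, "case", seed = s[1])
      control <- sample_cohort(model, n, "control", seed = s[2])
      test <- sample_cohort(model, n, "test", seed = s[3])
      case_forest <- build_tax(case, blocks)
      control_forest <- build_tax(control, blocks)
      case_rel <- anonymize(case, case_forest, blocks, epsilon = eps,
                            h = h, seed = s[4], rounding = rounding)
      control_rel <- anonymize(control, control_forest, blocks,
                               epsilon = eps, h = h, seed = s[5],
                               rounding = rounding)
      ur <- utility_report(case, control, case_rel, control_rel,
                           case_forest, control_forest, blocks, cutoffs)
      utility_rows[[length(utility_rows) + 1L]] <-
        cbind(data.frame(epsilon = eps, trial = t), ur)
      panel <- assign_minor_alleles(test, alleles = model$alleles)
      phat <- pool_frequencies_from_release(case_rel, case_forest, blocks,
                                            panel)
      if (attack_mode == "per_allele") {
        p_vec <- expand_per_allele(panel$p)
        phat_vec <- expand_per_allele(phat)
      } else {
        p_vec <- panel$p; phat_vec <- phat
      }
      case_stats <- lr_statistics(binarize(case, panel, attack_mode),
                                  p_vec, phat_vec)
      test_stats <- lr_statistics(binarize(test, panel, attack_mode),
                                  p_vec, phat_vec)
      pw <- power_at_fpr(case_stats, test_stats, fpr)
      power_rows[[length(power_rows) + 1L]] <-
        data.frame(epsilon = eps, trial = t, power = pw$power,
                   threshold = pw$threshold)
    }
  }
  utility <- do.call(rbind, utility_rows)
  power <- do.call(rbind, power_rows)
  metric_cols <- c("accuracy", "sensitivity", "precision", "f1",
                   "n_significant_truth")
  summary_utility <- do.call(rbind, lapply(split(
    utility, list(utility$epsilon, utility$cutoff)), function(d)
      cbind(data.frame(epsilon = d$epsilon[1], cutoff = d$cutoff[1]),
            as.data.frame(as.list(colMeans(d[metric_cols]))))))
  summary_utility <- summary_utility[order(summary_utility$epsilon,
                                           -summary_utility$cutoff), ]
  rownames(summary_utility) <- NULL
  summary_power <- do.call(rbind, lapply(split(power, power$epsilon),
    function(d) data.frame(epsilon = d$epsilon[1],
                           power = mean(d$power))))
  rownames(summary_power) <- NULL
  structure(list(
    config = list(scenario = scenario$name %||% "custom",
                  m = model$m, n_per_group = n,
                  n_effect = length(model$effect_snps), delta = model$delta,
                  epsilon = epsilon, h = h, block_size = block_size,
                  trials = trials, cutoffs = cutoffs, fpr = fpr,
                  attack_mode = attack_mode,
                  taxonomy_style = taxonomy_style, rounding = rounding,
                  seed = as.integer(seed),
                  model_digest = digest::digest(model, algo = "md5")),
    utility = summary_utility, attack = summary_power,
    per_trial = list(utility = utility, power = power)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cfg <- x$config
  cat("evaluation_report:", cfg$scenario, "| m =", cfg$m, ", n =",
      cfg$n_per_group, "/group,", cfg$trials, "trials\n")
  cat("mean utility (significant-SNP recovery):\n")
  print(x$utility, digits = 3)
  cat("mean attack power at", paste0(100 * cfg$fpr, "%"), "FPR:\n")
  print(x$attack, digits = 3)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @param per_trial include the per-trial tables (default TRUE).
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path, per_trial = TRUE) {
  stopifnot(inherits(report, "evaluation_report"))
  out <- list(config = report$config, utility = report$utility,
              attack = report$attack)
  if (per_trial) out$per_trial <- report$per_trial
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
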