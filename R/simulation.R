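## Simulation-study harness: operating characteristics of the permutation
## tests on cohorts from the synthetic generator, run end-to-end through
## classification and per-embryo summarisation.
##
## Scenario parameterisation. The generator applies `interaction_effect`
## on top of baseline + main effects, so the double-het rate is
## baseline + mP + mQ + interaction_effect and the no-intercept b3 truth is
## interaction_effect - baseline. Scenarios are therefore specified by
## `delta`, the synergy *excess over the additive sum* of the single-het
## rates, and the harness sets interaction_effect = baseline + delta:
## delta = 0 is the additive null (H0: b3 = 0 holds exactly on the
## probability scale), delta > 0 is synergy. For the two-group test, delta
## is the mutant main effect (delta = 0 is the null). With embryo_sd > 0
## the reported truth is the marginal (logit-normal averaged) contrast from
## the cohort truth table, which is what the estimator is unbiased for.

#' Rejection rates of the permutation tests on synthetic cohorts
#'
#' For each effect size in `deltas`, generates `n_reps` cohorts, runs the
#' full scoring pipeline (materialise records, classify, summarise per
#' embryo) and the chosen permutation test on the selected defect
#' category, and reports the rejection fraction at the configured alpha
#' with its binomial standard error, together with the mean estimated
#' coefficient and the true (marginal) contrast.
#'
#' @param test `"interaction"` (synergy test on single-het P, single-het Q
#'   and double-het cohorts) or `"two_group"` (control vs mutant).
#' @param deltas effect sizes: synergy excess over the additive sum
#'   (interaction) or mutant main effect (two-group), probability scale.
#' @param n_reps simulated cohorts per effect size.
#' @param category defect category scored (`"tin_symmetric"` default: its
#'   generated and observable rates coincide exactly).
#' @param n_embryos embryos per genotype group.
#' @param baseline_rate baseline category rates, as in [generator_config()].
#' @param embryo_sd logit-scale per-embryo random-effect SD.
#' @param main_effect_p,main_effect_q single-heterozygote main effects on
#'   `category` (interaction test only).
#' @param perm_config a [perm_config()]; its `seed` is ignored here (the
#'   harness manages per-replicate seeds).
#' @param seed seed for the whole study. Replicate `i` runs under a seed
#'   derived from `seed` and `i` that is shared across all `deltas`
#'   (common random numbers), so power comparisons across effect sizes are
#'   positively coupled.
#' @return data.frame with one row per delta: `test`, `delta`, `n_reps`,
#'   `n_reject`, `rejection_rate`, `se_rejection`, `mean_coef`, `se_coef`,
#'   `truth_coef`, `alpha`, `n_permutations`.
#' @export
simulation_study <- function(test = c("interaction", "two_group"),
                             deltas = c(0, 0.05, 0.10, 0.15),
                             n_reps = 500,
                             category = "tin_symmetric",
                             n_embryos = 15,
                             baseline_rate = c(tin_symmetric = 0.02,
                                               svp_earlier = 0.01,
                                               svp_asymmetric = 0.005),
                             embryo_sd = 0.5,
                             main_effect_p = 0.04,
                             main_effect_q = 0.04,
                             perm_config = heartperm::perm_config(
                               n_permutations = 499),
                             seed = 1) {
  test <- match.arg(test)
  stopifnot(n_reps >= 1)
  pc <- perm_config
  pc$seed <- NULL  # permutations draw from the study stream
  prop_col <- paste0("prop_", category)

  make_config <- function(delta) {
    if (test == "interaction") {
      base_cat <- baseline_rate[[category]] %||% 0
      generator_config(
        n_embryos = c(het_p = n_embryos, het_q = n_embryos,
                      double = n_embryos),
        baseline_rate = baseline_rate,
        embryo_sd = embryo_sd,
        main_effect = list(
          het_p = stats::setNames(main_effect_p, category),
          het_q = stats::setNames(main_effect_q, category),
          double = stats::setNames(main_effect_p + main_effect_q, category)),
        interaction_effect = stats::setNames(base_cat + delta, category),
        double_het = "double",
        roles = c(het_p = "single_het_1", het_q = "single_het_2",
                  double = "double_het"),
        seed = NULL)
    } else {
      generator_config(
        n_embryos = c(control = n_embryos, mutant = n_embryos),
        baseline_rate = baseline_rate,
        embryo_sd = embryo_sd,
        main_effect = list(mutant = stats::setNames(delta, category)),
        seed = NULL)
    }
  }

  run_one <- function(cfg) {
    cohort <- generate_cohort(cfg)
    summaries <- summarize_embryos(cohort$records)
    y <- summaries[[prop_col]]
    if (test == "interaction") {
      ip <- as.integer(summaries$genotype %in% c("het_p", "double"))
      iq <- as.integer(summaries$genotype %in% c("het_q", "double"))
      res <- interaction_perm_test(y, ip, iq, config = pc)
    } else {
      res <- two_group_perm_test(y, summaries$genotype, config = pc,
                                 ref = "control")
    }
    c(coef = res$coefficient, reject = as.numeric(res$p_value <= pc$alpha))
  }

  rep_seed <- function(i) (abs(as.integer(seed)) %% 20000L) * 100003L + i
  rows <- lapply(deltas, function(delta) {
    cfg <- make_config(delta)
    truth <- cohort_truth(cfg)
    truth_coef <- if (test == "interaction") {
      truth$interaction$excess_marginal[
        truth$interaction$category == category]
    } else {
      r <- truth$rates
      r$rate_marginal[r$genotype == "mutant" & r$category == category] -
        r$rate_marginal[r$genotype == "control" & r$category == category]
    }
    out <- vapply(seq_len(n_reps), function(i)
      eval_with_seed(rep_seed(i), function() run_one(cfg)), numeric(2))
    n_reject <- sum(out["reject", ])
    rate <- n_reject / n_reps
    data.frame(
      test = test, delta = delta, n_reps = n_reps, n_reject = n_reject,
      rejection_rate = rate,
      se_rejection = sqrt(rate * (1 - rate) / n_reps),
      mean_coef = mean(out["coef", ]),
      se_coef = stats::sd(out["coef", ]) / sqrt(n_reps),
      truth_coef = truth_coef, alpha = pc$alpha,
      n_permutations = pc$n_permutations,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
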