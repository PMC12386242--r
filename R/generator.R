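## Synthetic embryo cohorts.
##
## The generator reproduces the statistical structure the inference assumes:
## per-embryo correlated defect probabilities (a shared embryo-level random
## effect on the logit scale), genotype main effects on the probability
## scale, and an optional interaction (synergy) shift for the double
## heterozygote. Effects are additive on the probability scale so that the
## "additive expectation" of a genetic-interaction assay — double-het rate
## equal to the sum of the two single-het rates — is exactly representable;
## the within-embryo correlation enters on the logit scale, where a mean-zero
## Gaussian effect keeps per-hemisegment probabilities in (0, 1).
##
## Defective hemisegments are materialised through their diagnostic count
## signatures so that classify_hemisegments() recovers exactly the category
## that was generated:
##   tin_symmetric  -> tin_cc drawn from {3, 5} (minimal +/-1 deviations)
##   svp_earlier    -> (svp_cc, svp_pc) uniform over {(1,1), (3,3)}
##   svp_asymmetric -> uniform over {(1,3), (3,1), (2,1)}; (2,1) sets the
##                     enlarged-nucleus (karyokinesis) flag
## If both Svp categories fire on one hemisegment, svp_earlier takes
## precedence (deterministic, documented; see cohort truth for the
## resulting observable asymmetric rate).

.generator_categories <- c("tin_symmetric", "svp_earlier", "svp_asymmetric")

#' Configure the synthetic-cohort generator
#'
#' @param n_embryos named integer vector: embryos per genotype, e.g.
#'   `c(wildtype = 15, mutant = 22)`. Generation order is name order.
#' @param baseline_rate named probabilities for the three generated defect
#'   categories (`tin_symmetric`, `svp_earlier`, `svp_asymmetric`) in the
#'   reference (no-effect) condition.
#' @param embryo_sd standard deviation (logit scale, >= 0) of the per-embryo
#'   random effect shared by all hemisegments of one embryo; 0 gives
#'   independent (binomial) hemisegments.
#' @param main_effect named list: genotype -> named numeric additive shifts
#'   (probability scale) per category. Genotypes absent from the list have
#'   no main effect.
#' @param interaction_effect additive probability-scale shift applied, per
#'   category, to the genotypes named in `double_het`. Scalar values are
#'   recycled across the three categories.
#' @param double_het character vector of genotype(s) receiving
#'   `interaction_effect` (typically the double heterozygote).
#' @param roles optional named character vector mapping genotypes to roles
#'   (`"single_het_1"`, `"single_het_2"`, `"double_het"`, `"control"`,
#'   `"wildtype"`, `"mutant"`); used to compute interaction truth.
#' @param segments data.frame with columns `segment`, `side` defining the
#'   hemisegments scored per embryo; default A2-A8 bilaterally (14).
#' @param assay assay mode of the materialised records.
#' @param tin_defect_counts candidate `tin_cc` values for a materialised
#'   Tin-lineage defect.
#' @param prob_ceiling upper clip for all realised probabilities.
#' @param seed integer seed; the seed fully determines the cohort.
#'   `NULL` draws from the current RNG stream.
#' @return object of class `"generator_config"`.
#' @export
generator_config <- function(n_embryos = c(wildtype = 15, mutant = 15),
                             baseline_rate = c(tin_symmetric = 0.025,
                                               svp_earlier = 0.01,
                                               svp_asymmetric = 0.005),
                             embryo_sd = 0.5,
                             main_effect = list(),
                             interaction_effect = 0,
                             double_het = character(),
                             roles = NULL,
                             segments = NULL,
                             assay = c("svp_lacz", "svp_antibody"),
                             tin_defect_counts = c(3L, 5L),
                             prob_ceiling = 0.95,
                             seed = NULL) {
  assay <- match.arg(assay)
  if (is.null(names(n_embryos)) || any(!nzchar(names(n_embryos))))
    stop("`n_embryos` must be a named vector (genotype -> count)")
  if (any(!is_count(n_embryos) | n_embryos < 1))
    stop("zero embryos requested for genotype(s): ",
         paste(names(n_embryos)[!is_count(n_embryos) | n_embryos < 1],
               collapse = ", "))
  cats <- .generator_categories
  baseline_rate <- baseline_rate[cats]
  names(baseline_rate) <- cats
  baseline_rate[is.na(baseline_rate)] <- 0
  if (any(baseline_rate < 0 | baseline_rate > 1))
    stop("baseline rates must be probabilities")
  stopifnot(length(embryo_sd) == 1L, embryo_sd >= 0)
  if (length(interaction_effect) == 1L && is.null(names(interaction_effect)))
    interaction_effect <- stats::setNames(rep(interaction_effect, 3L), cats)
  interaction_effect <- interaction_effect[cats]
  names(interaction_effect) <- cats
  interaction_effect[is.na(interaction_effect)] <- 0
  main_effect <- lapply(main_effect, function(x) {
    full <- stats::setNames(numeric(3L), cats)
    full[intersect(names(x), cats)] <- x[intersect(names(x), cats)]
    full
  })
  if (is.null(segments))
    segments <- expand.grid(segment = segment_names(), side = c("L", "R"),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("segment", "side") %in% names(segments)))
  if (!all(double_het %in% names(n_embryos)))
    stop("double_het genotype(s) not in n_embryos: ",
         paste(setdiff(double_het, names(n_embryos)), collapse = ", "))
  structure(list(
    n_embryos = n_embryos, baseline_rate = baseline_rate,
    embryo_sd = embryo_sd, main_effect = main_effect,
    interaction_effect = interaction_effect, double_het = double_het,
    roles = roles, segments = segments, assay = assay,
    tin_defect_counts = as.integer(tin_defect_counts),
    prob_ceiling = prob_ceiling, seed = seed
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat("  genotypes: ",
      paste(sprintf("%s (n=%d)", names(x$n_embryos), x$n_embryos),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  hemisegments/embryo: %d   assay: %s   embryo_sd: %g\n",
              nrow(x$segments), x$assay, x$embryo_sd))
  cat("  baseline rates: ",
      paste(sprintf("%s=%g", names(x$baseline_rate), x$baseline_rate),
            collapse = ", "), "\n", sep = "")
  if (length(x$double_het))
    cat("  interaction on ", paste(x$double_het, collapse = ", "), ": ",
        paste(sprintf("%g", x$interaction_effect), collapse = "/"),
        "\n", sep = "")
  invisible(x)
}

## Configured (probability-scale, clipped) defect rate for one genotype.
configured_rate <- function(config, genotype) {
  p <- config$baseline_rate
  me <- config$main_effect[[genotype]]
  if (!is.null(me)) p <- p + me
  if (genotype %in% config$double_het) p <- p + config$interaction_effect
  clip_prob(p, config$prob_ceiling)
}

#' Marginal (embryo-averaged) defect rate under the logit-normal model
#'
#' With a per-embryo effect u ~ N(0, sd^2), the hemisegment-level defect
#' probability is `min(plogis(qlogis(p) + u), ceiling)`; the marginal rate
#' averages this over u by numerical integration. With `embryo_sd = 0` it
#' is `p` itself. This is the expected per-embryo defect proportion, i.e.
#' the estimand the permutation tests compare.
#'
#' @param p configured probability-scale rate (already clipped).
#' @param embryo_sd logit-scale standard deviation.
#' @param prob_ceiling upper probability clip.
#' @return scalar marginal rate.
#' @export
marginal_defect_rate <- function(p, embryo_sd, prob_ceiling = 0.95) {
  p <- clip_prob(p, prob_ceiling)
  if (p <= 0 || embryo_sd == 0) return(p)
  stats::integrate(function(u)
    pmin(stats::plogis(stats::qlogis(p) + u), prob_ceiling) *
      stats::dnorm(u, 0, embryo_sd),
    -Inf, Inf, rel.tol = 1e-10)$value
}

## Truth tables recorded with each cohort: configured, marginal, and
## observable rates per genotype x category. The observable asymmetric rate
## accounts for the earlier-category materialisation precedence (the two
## category draws are independent, so P(asym visible) = m_asym * (1 - m_earl)).
cohort_truth <- function(config) {
  cats <- .generator_categories
  rows <- lapply(names(config$n_embryos), function(g) {
    pc <- configured_rate(config, g)
    marg <- vapply(cats, function(cat)
      marginal_defect_rate(pc[[cat]], config$embryo_sd, config$prob_ceiling),
      numeric(1))
    obs <- marg
    obs["svp_asymmetric"] <- marg[["svp_asymmetric"]] *
      (1 - marg[["svp_earlier"]])
    data.frame(genotype = g, category = cats,
               rate_configured = unname(pc), rate_marginal = unname(marg),
               rate_observable = unname(obs), stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL
  interaction <- NULL
  roles <- config$roles
  if (!is.null(roles) &&
      all(c("single_het_1", "single_het_2", "double_het") %in% roles)) {
    gp <- names(roles)[roles == "single_het_1"][1L]
    gq <- names(roles)[roles == "single_het_2"][1L]
    gd <- names(roles)[roles == "double_het"][1L]
    pick <- function(g, col) rates[[col]][rates$genotype == g]
    interaction <- data.frame(
      category = cats,
      excess_configured = pick(gd, "rate_configured") -
        pick(gp, "rate_configured") - pick(gq, "rate_configured"),
      excess_marginal = pick(gd, "rate_marginal") -
        pick(gp, "rate_marginal") - pick(gq, "rate_marginal"),
      excess_observable = pick(gd, "rate_observable") -
        pick(gp, "rate_observable") - pick(gq, "rate_observable"),
      stringsAsFactors = FALSE
    )
  }
  list(rates = rates, interaction = interaction)
}

## Core sampler for one genotype block; assumes the RNG stream is set.
sample_genotype_block <- function(config, genotype, n_embryos, id_prefix) {
  n_h <- nrow(config$segments)
  cats <- .generator_categories
  p <- configured_rate(config, genotype)

  ## per-embryo effects (one per category), then per-hemisegment Bernoulli
  prob <- matrix(0, n_embryos, 3L)
  for (k in 1:3) {
    pk <- p[[cats[k]]]
    if (config$embryo_sd == 0) {
      prob[, k] <- pk
    } else {
      if (pk <= 0) {
        warning("configured rate for ", cats[k], " is <= 0 after clipping; ",
                "substituting 1e-6 for the logit transform")
        pk <- 1e-6
      }
      u <- stats::rnorm(n_embryos, 0, config$embryo_sd)
      prob[, k] <- pmin(stats::plogis(stats::qlogis(pk) + u),
                        config$prob_ceiling)
    }
  }
  n <- n_embryos * n_h
  embryo_row <- rep(seq_len(n_embryos), each = n_h)
  defect <- matrix(stats::runif(n * 3L), n, 3L) < prob[embryo_row, , drop = FALSE]

  wt <- wildtype_counts()
  tin_cc <- rep.int(wt[["tin_cc"]], n)
  svp_cc <- rep.int(wt[["svp_cc"]], n)
  svp_pc <- rep.int(wt[["svp_pc"]], n)
  enlarged <- rep.int(FALSE, n)

  i_tin <- which(defect[, 1L])
  if (length(i_tin))
    tin_cc[i_tin] <- config$tin_defect_counts[
      sample.int(length(config$tin_defect_counts), length(i_tin),
                 replace = TRUE)]
  i_earl <- which(defect[, 2L])
  if (length(i_earl)) {
    sz <- c(1L, 3L)[sample.int(2L, length(i_earl), replace = TRUE)]
    svp_cc[i_earl] <- sz
    svp_pc[i_earl] <- sz
  }
  i_asym <- which(defect[, 3L] & !defect[, 2L])  # earlier takes precedence
  if (length(i_asym)) {
    patterns <- rbind(c(1L, 3L), c(3L, 1L), c(2L, 1L))
    pick <- sample.int(3L, length(i_asym), replace = TRUE)
    svp_cc[i_asym] <- patterns[pick, 1L]
    svp_pc[i_asym] <- patterns[pick, 2L]
    enlarged[i_asym[pick == 3L]] <- TRUE
  }
  if (config$assay == "svp_antibody") svp_pc <- rep(NA_integer_, n)

  data.frame(
    embryo_id = sprintf("%s_e%03d", id_prefix, embryo_row),
    genotype = genotype,
    segment = rep(config$segments$segment, times = n_embryos),
    side = rep(config$segments$side, times = n_embryos),
    tin_cc = tin_cc, svp_cc = svp_cc, svp_pc = svp_pc,
    enlarged_svp_nucleus = enlarged, assay = config$assay,
    stringsAsFactors = FALSE
  )
}

#' Sample the hemisegment records of one embryo
#'
#' @param config a [generator_config()].
#' @param genotype genotype name (must appear in `config$n_embryos`).
#' @param embryo_id identifier for the generated embryo.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return records data.frame with one row per configured hemisegment.
#' @export
sample_embryo <- function(config, genotype, embryo_id = "embryo_1",
                          seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!genotype %in% names(config$n_embryos))
    stop("unknown genotype: ", genotype)
  eval_with_seed(seed, function() {
    rec <- sample_genotype_block(config, genotype, 1L, id_prefix = genotype)
    rec$embryo_id <- as.character(embryo_id)
    rec
  })
}

#' Generate a full synthetic cohort
#'
#' Samples every configured genotype in name order under one RNG stream
#' seeded from `config$seed`, and records the generating truth (configured,
#' marginal and observable per-category rates, plus the interaction excess
#' when genotype roles identify the two single heterozygotes and the double
#' heterozygote).
#'
#' @param config a [generator_config()].
#' @return object of class `"synthetic_cohort"`: a list with elements
#'   `records` (validated records data.frame), `truth` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  eval_with_seed(config$seed, function() {
    blocks <- lapply(names(config$n_embryos), function(g)
      sample_genotype_block(config, g, config$n_embryos[[g]], id_prefix = g))
    records <- do.call(rbind, blocks)
    rownames(records) <- NULL
    structure(list(records = records, truth = cohort_truth(config),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d records, %d embryos, %d genotypes (%s)\n",
              nrow(x$records), length(unique(x$records$embryo_id)),
              length(x$config$n_embryos), x$config$assay))
  invisible(x)
}

#' Write a cohort as a count CSV plus truth JSON sidecar
#'
#' @param cohort a `"synthetic_cohort"`.
#' @param dir output directory (created if needed).
#' @param stem file name stem.
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_counts.csv"))
  json <- file.path(dir, paste0(stem, "_truth.json"))
  write_counts(cohort$records, csv)
  jsonlite::write_json(cohort$truth, json, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(c(counts = csv, truth = json))
}
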