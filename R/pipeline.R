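## End-to-end orchestration: read counts -> classify -> summarise ->
## aggregate -> permutation tests -> report tables.
##
## Genotype roles drive the testing mode:
##   two-group:    roles {control (or wildtype), mutant}
##   interaction:  roles {single_het_1, single_het_2, double_het},
##                 optionally control (used in the fit only when
##                 with_intercept = TRUE)
## Report rows mirror figure-legend statistics: pooled percentage per
## genotype and category, embryo and hemisegment counts, the test p-value,
## and — for double-heterozygote rows — the expected percentage under pure
## additivity (sum of the two single-het pooled percentages, the "dashed
## line" of an interaction bar plot).

pipeline_roles <- c("control", "wildtype", "mutant",
                    "single_het_1", "single_het_2", "double_het")

#' Run the full defect-scoring and inference pipeline
#'
#' @param records hemisegment count records (data.frame), or `NULL` to read
#'   from `input`.
#' @param input path to a count CSV/TSV (used when `records` is `NULL`).
#' @param roles named character vector mapping every genotype present to a
#'   role: `control`/`wildtype` + `mutant` for a two-group run, or
#'   `single_het_1` + `single_het_2` + `double_het` (+ optional `control`)
#'   for an interaction run.
#' @param perm_config a [perm_config()]; the same seed is applied to each
#'   category's test, so a rerun reproduces every p-value exactly.
#' @param categories defect categories to test; default: all scored
#'   categories except `unclassified_svp`.
#' @param with_intercept interaction runs only: include an intercept and
#'   the control embryos in the interaction fit.
#' @param out_dir optional output directory; when given, writes
#'   `embryo_summaries.csv`, `genotype_table.csv`, `report.csv`,
#'   `tests.json` and a human-readable `report.txt`.
#' @param verbose log the applied defaults (N, seed, tie rule, tail,
#'   intercept mode) via `message()`.
#' @return list with `records`, `summaries`, `genotype_table`, `tests`
#'   (one `"perm_test"` per category), `report` (data.frame of report
#'   rows) and `files` (written paths, if any).
#' @export
run_pipeline <- function(records = NULL, input = NULL, roles,
                         perm_config = heartperm::perm_config(),
                         categories = NULL, with_intercept = FALSE,
                         out_dir = NULL, verbose = TRUE) {
  pc <- perm_config
  stopifnot(inherits(pc, "perm_config"))
  if (is.null(records)) {
    if (is.null(input)) stop("provide `records` or `input`")
    records <- read_counts(input)
  }
  records <- classify_hemisegments(records)

  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    stop("`roles` must be a named vector (genotype -> role)")
  bad_role <- setdiff(roles, pipeline_roles)
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "))
  genos <- unique(records$genotype)
  uncovered <- setdiff(genos, names(roles))
  if (length(uncovered))
    stop("genotype(s) without a role: ", paste(uncovered, collapse = ", "))

  interaction_mode <-
    all(c("single_het_1", "single_het_2", "double_het") %in% roles)
  two_group_mode <- "mutant" %in% roles &&
    any(c("control", "wildtype") %in% roles)
  if (!interaction_mode && !two_group_mode)
    stop("roles must define either a two-group run (control/wildtype + ",
         "mutant) or an interaction run (single_het_1 + single_het_2 + ",
         "double_het)")

  summaries <- summarize_embryos(records)
  genotype_table <- aggregate_genotypes(summaries)
  assay <- unique(summaries$assay)
  categories <- categories %||%
    setdiff(defect_categories(assay), "unclassified_svp")

  if (verbose)
    message(sprintf(
      "permutation settings: N=%d, seed=%s, tie_rule=%s, tail=%s, %s",
      pc$n_permutations, pc$seed %||% "<stream>", pc$tie_rule, pc$tail,
      if (interaction_mode)
        sprintf("interaction model %s intercept",
                if (with_intercept) "with" else "without")
      else "two-group model with intercept"))

  role_of <- function(g) unname(roles[g])
  summaries$role <- role_of(summaries$genotype)

  tests <- lapply(categories, function(cat) {
    y_col <- paste0("prop_", cat)
    if (interaction_mode) {
      keep_roles <- c("single_het_1", "single_het_2", "double_het")
      if (with_intercept) keep_roles <- c(keep_roles, "control", "wildtype")
      s <- summaries[summaries$role %in% keep_roles, , drop = FALSE]
      ip <- as.integer(s$role %in% c("single_het_1", "double_het"))
      iq <- as.integer(s$role %in% c("single_het_2", "double_het"))
      interaction_perm_test(s[[y_col]], ip, iq, config = pc,
                            with_intercept = with_intercept)
    } else {
      s <- summaries[summaries$role %in%
                       c("control", "wildtype", "mutant"), , drop = FALSE]
      two_group_perm_test(
        s[[y_col]], factor(s$role == "mutant", levels = c(FALSE, TRUE),
                           labels = c("reference", "mutant")),
        config = pc, ref = "reference")
    }
  })
  names(tests) <- categories

  report <- build_report(genotype_table, roles, categories, tests,
                         interaction_mode)

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      embryo_summaries = file.path(out_dir, "embryo_summaries.csv"),
      genotype_table = file.path(out_dir, "genotype_table.csv"),
      report = file.path(out_dir, "report.csv"),
      tests = file.path(out_dir, "tests.json"),
      report_txt = file.path(out_dir, "report.txt"))
    utils::write.csv(summaries, paths["embryo_summaries"], row.names = FALSE)
    utils::write.csv(genotype_table, paths["genotype_table"],
                     row.names = FALSE)
    utils::write.csv(report, paths["report"], row.names = FALSE, na = "")
    jsonlite::write_json(
      lapply(tests, function(t) list(
        coefficient = t$coefficient, n = t$exceedances,
        N = t$n_permutations, p_value = t$p_value, scheme = t$scheme,
        seed = t$seed, exhaustive = t$exhaustive, tail = t$tail,
        tie_rule = t$tie_rule)),
      paths["tests"], auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(report_lines(report, tests), paths["report_txt"])
    files <- paths
  }

  list(records = records, summaries = summaries,
       genotype_table = genotype_table, tests = tests, report = report,
       files = files)
}

build_report <- function(genotype_table, roles, categories, tests,
                         interaction_mode) {
  tab <- genotype_table[genotype_table$category %in% categories, ,
                        drop = FALSE]
  tab$role <- unname(roles[tab$genotype])
  tab$p_value <- NA_real_
  tab$expected_additive_percent <- NA_real_
  tab$synergy <- NA_character_
  for (cat in categories) {
    t <- tests[[cat]]
    i_cat <- tab$category == cat
    if (interaction_mode) {
      dbl <- i_cat & tab$role == "double_het"
      tab$p_value[dbl] <- t$p_value
      tab$expected_additive_percent[dbl] <-
        tab$percent[i_cat & tab$role == "single_het_1"] +
        tab$percent[i_cat & tab$role == "single_het_2"]
      tab$synergy[dbl] <- synergy_call(t)
    } else {
      tab$p_value[i_cat & tab$role == "mutant"] <- t$p_value
    }
  }
  rownames(tab) <- NULL
  tab
}

report_lines <- function(report, tests) {
  lines <- sprintf(
    "%s [%s] %s: %s of hemisegments defective (%d/%d, %d embryos)%s%s",
    report$genotype, report$role, report$category,
    format_percent(report$percent), report$n_defects,
    report$n_hemisegments, report$n_embryos,
    ifelse(is.na(report$expected_additive_percent), "",
           sprintf("; additive expectation %s",
                   format_percent(report$expected_additive_percent))),
    ifelse(is.na(report$p_value), "",
           sprintf("; p = %s%s", format_pvalue(report$p_value),
                   ifelse(is.na(report$synergy), "",
                          paste0(" [", report$synergy, "]")))))
  c("Cardiac cell-division defect report", "", lines)
}
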