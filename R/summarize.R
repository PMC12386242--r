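## Per-embryo summaries and per-genotype aggregation.
##
## The embryo is the unit of inference: hemisegments within one embryo are
## correlated in their defect propensity, so downstream permutation tests
## operate on the per-embryo defect *proportions* (the response Y_j), never
## on pooled hemisegment counts.

#' Summarise defect calls per embryo
#'
#' Counts, for each embryo, the number of scored hemisegments and the number
#' falling in each defect category, and computes the per-embryo proportion
#' (defects / hemisegments, exact). Records are classified first if the
#' defect-call columns are absent.
#'
#' @param records validated (optionally already classified) records.
#' @return data.frame with one row per embryo: `embryo_id`, `genotype`,
#'   `assay`, `n_hemisegments`, then a count column `n_<category>` and a
#'   proportion column `prop_<category>` for every applicable category.
#' @export
summarize_embryos <- function(records) {
  if (!all(c("tin_symmetric", "svp_combined") %in% names(records)))
    records <- classify_hemisegments(records)
  else validate_records(records[, record_columns()])

  assays <- unique(records$assay)
  if (length(assays) > 1L)
    stop("mixed assay modes in one dataset: ", paste(assays, collapse = ", "))
  cats <- defect_categories(assays)

  ids <- unique(records$embryo_id)
  f <- factor(records$embryo_id, levels = ids)
  out <- data.frame(
    embryo_id = ids,
    genotype = as.character(tapply(records$genotype, f, `[`, 1L)),
    assay = assays,
    n_hemisegments = as.integer(tabulate(f, nbins = length(ids))),
    stringsAsFactors = FALSE
  )
  for (cat in cats) {
    m <- rowsum(as.integer(records[[cat]]), records$embryo_id)
    n_def <- as.integer(m[ids, 1L])
    out[[paste0("n_", cat)]] <- n_def
    out[[paste0("prop_", cat)]] <- n_def / out$n_hemisegments
  }
  rownames(out) <- NULL
  out
}

#' Aggregate per-embryo summaries into a per-genotype table
#'
#' For each genotype and defect category, reports the pooled defective
#' hemisegment count, pooled hemisegment count, pooled percentage
#' (100 * sum(defects) / sum(hemisegments) — the figure-legend statistic),
#' and the unweighted mean of per-embryo proportions (the quantity the
#' permutation tests model).
#'
#' @param summaries output of [summarize_embryos()].
#' @return long data.frame: `genotype`, `category`, `n_embryos`,
#'   `n_hemisegments`, `n_defects`, `percent`, `mean_proportion`.
#' @export
aggregate_genotypes <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  assays <- unique(summaries$assay)
  if (length(assays) > 1L)
    stop("mixed assay modes: ", paste(assays, collapse = ", "))
  cats <- defect_categories(assays)

  genos <- unique(summaries$genotype)
  rows <- lapply(genos, function(g) {
    s <- summaries[summaries$genotype == g, , drop = FALSE]
    h <- sum(s$n_hemisegments)
    data.frame(
      genotype = g,
      category = cats,
      n_embryos = nrow(s),
      n_hemisegments = h,
      n_defects = vapply(cats, function(cat)
        sum(s[[paste0("n_", cat)]]), integer(1)),
      percent = vapply(cats, function(cat)
        100 * sum(s[[paste0("n_", cat)]]) / h, numeric(1)),
      mean_proportion = vapply(cats, function(cat)
        mean(s[[paste0("prop_", cat)]]), numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
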