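# Fixture builders: everything is generated in code, no stored data.

# Records for one embryo; `counts` is a matrix/data.frame with columns
# (tin_cc, svp_cc, svp_pc), one row per hemisegment (<= 14), assigned to
# segments A2-A8 left then right.
embryo_records <- function(counts, embryo_id = "e1", genotype = "wt",
                           assay = "svp_lacz") {
  counts <- as.matrix(counts)
  segs <- expand.grid(segment = paste0("A", 2:8), side = c("L", "R"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(counts)
  stopifnot(n <= 14)
  data.frame(
    embryo_id = embryo_id, genotype = genotype,
    segment = segs$segment[seq_len(n)], side = segs$side[seq_len(n)],
    tin_cc = counts[, 1], svp_cc = counts[, 2],
    svp_pc = if (assay == "svp_lacz") counts[, 3] else NA_real_,
    enlarged_svp_nucleus = FALSE, assay = assay,
    stringsAsFactors = FALSE
  )
}

# n wild-type hemisegment count rows
wt_counts <- function(n = 14) {
  matrix(rep(c(4, 2, 2), each = n), ncol = 3,
         dimnames = list(NULL, c("tin_cc", "svp_cc", "svp_pc")))
}

# A clean multi-embryo dataset
clean_cohort_records <- function(n_embryos, genotype = "wt",
                                 assay = "svp_lacz") {
  do.call(rbind, lapply(seq_len(n_embryos), function(i)
    embryo_records(wt_counts(), embryo_id = sprintf("%s_%02d", genotype, i),
                   genotype = genotype, assay = assay)))
}

# All permutations of a vector (brute-force oracle; n <= 7)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# Dense projection-matrix oracle for orthogonalization
project_out_oracle <- function(Z, g) {
  Z <- as.matrix(Z)
  P <- Z %*% solve(t(Z) %*% Z) %*% t(Z)
  as.vector(g - P %*% g)
}
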