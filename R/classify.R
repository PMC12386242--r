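## Defect classification.
##
## A wild-type hemisegment carries 4 Tin CCs, 2 Svp CCs and 2 Svp PCs,
## produced by stereotyped progenitor divisions: the Tin superprogenitor
## divides symmetrically twice (1 -> 2 -> 4 CCs); the Svp superprogenitor
## divides symmetrically once into two Svp progenitors, each of which then
## divides asymmetrically into one CC and one PC. Deviations from the
## expected counts are therefore diagnostic of which division failed:
##
##   tin_symmetric    tin_cc != 4 (any error in the two symmetric rounds)
##   svp_earlier      (svp_cc, svp_pc) in {(1,1), (3,3)}: the earlier
##                    symmetric superprogenitor division produced 1 or 3
##                    progenitors instead of 2, each then dividing normally
##   svp_asymmetric   (svp_cc, svp_pc) in {(1,3), (3,1)}: one asymmetric
##                    division produced two like daughters; or (2,1), the
##                    karyokinesis-arrest signature (one enlarged Svp CC
##                    nucleus standing in for a CC/PC pair)
##   unclassified_svp any other (svp_cc, svp_pc) pattern; counted in
##                    denominators but in no category numerator
##
## In antibody mode the PCs are invisible, so the two Svp categories
## collapse into a single combined flag svp_combined := (svp_cc != 2).

.svp_earlier_patterns <- c("1/1", "3/3")
.svp_asymmetric_patterns <- c("1/3", "3/1", "2/1")

#' Defect categories scored in a given assay mode
#'
#' @param assay `"svp_lacz"` or `"svp_antibody"`.
#' @return character vector of category names.
#' @export
defect_categories <- function(assay = c("svp_lacz", "svp_antibody")) {
  assay <- match.arg(assay)
  if (assay == "svp_lacz")
    c("tin_symmetric", "svp_earlier", "svp_asymmetric", "unclassified_svp")
  else c("tin_symmetric", "svp_combined")
}

#' Classify hemisegments into cell-division defect categories
#'
#' Applies the deterministic decision table mapping each hemisegment's
#' (tin_cc, svp_cc, svp_pc) counts to defect-category flags. Tin and Svp
#' defects are scored independently: one hemisegment may carry both. In
#' lacZ mode, at most one of `svp_earlier`, `svp_asymmetric`,
#' `unclassified_svp` is set; in antibody mode only `svp_combined` applies
#' and the lacZ-only flags are `NA`.
#'
#' @param records validated records data.frame (see [validate_records()]).
#' @return the records with logical columns `tin_symmetric`, `svp_earlier`,
#'   `svp_asymmetric`, `unclassified_svp`, `svp_combined` appended.
#' @examples
#' rec <- data.frame(embryo_id = "e1", genotype = "wt", segment = "A2",
#'                   side = "L", tin_cc = 4, svp_cc = 3, svp_pc = 1,
#'                   enlarged_svp_nucleus = FALSE, assay = "svp_lacz")
#' classify_hemisegments(rec)$svp_asymmetric
#' @export
classify_hemisegments <- function(records) {
  records <- validate_records(records)
  lacz <- records$assay == "svp_lacz"
  pat <- paste(records$svp_cc, records$svp_pc, sep = "/")

  records$tin_symmetric <- records$tin_cc != 4L
  records$svp_earlier <- ifelse(lacz, pat %in% .svp_earlier_patterns, NA)
  records$svp_asymmetric <- ifelse(lacz, pat %in% .svp_asymmetric_patterns, NA)
  records$unclassified_svp <- ifelse(
    lacz, !(pat %in% c("2/2", .svp_earlier_patterns,
                       .svp_asymmetric_patterns)), NA)
  records$svp_combined <- ifelse(!lacz, records$svp_cc != 2L, NA)
  records
}

#' Simulate the wild-type cardiac progenitor lineages
#'
#' Expands a single superprogenitor through the stereotyped division
#' program of the Drosophila heart-tube lineages and returns the resulting
#' cell-type counts. The Tin superprogenitor undergoes `symmetric_rounds`
#' rounds of symmetric division, all daughters being cardiac cells. The
#' Svp superprogenitor undergoes one symmetric round into Svp progenitors,
#' each of which divides asymmetrically into one cardiac and one
#' pericardial cell.
#'
#' @param lineage `"tin"` or `"svp"`.
#' @param symmetric_rounds number of symmetric division rounds (default 2
#'   for Tin, 1 for Svp — the wild-type program).
#' @return named integer vector of cell counts: `c(cc = ...)` for Tin,
#'   `c(cc = ..., pc = ...)` for Svp.
#' @examples
#' simulate_lineage("tin")          # c(cc = 4)
#' simulate_lineage("svp")          # c(cc = 2, pc = 2)
#' simulate_lineage("svp", symmetric_rounds = 0)  # one progenitor: 1 CC, 1 PC
#' @export
simulate_lineage <- function(lineage = c("tin", "svp"),
                             symmetric_rounds = NULL) {
  lineage <- match.arg(lineage)
  symmetric_rounds <- symmetric_rounds %||% (if (lineage == "tin") 2L else 1L)
  stopifnot(is_count(symmetric_rounds))
  ## symmetric rounds: every cell divides into two identical daughters
  progenitors <- 1L
  for (i in seq_len(symmetric_rounds)) progenitors <- 2L * progenitors
  if (lineage == "tin") {
    c(cc = progenitors)
  } else {
    ## terminal asymmetric division: each progenitor -> one CC + one PC
    c(cc = progenitors, pc = progenitors)
  }
}

#' Expected wild-type hemisegment cell counts
#'
#' Derived from [simulate_lineage()], not hard-coded: 4 Tin CCs, 2 Svp CCs,
#' 2 Svp PCs.
#'
#' @return named integer vector `c(tin_cc = 4, svp_cc = 2, svp_pc = 2)`.
#' @export
wildtype_counts <- function() {
  tin <- simulate_lineage("tin")
  svp <- simulate_lineage("svp")
  c(tin_cc = unname(tin["cc"]), svp_cc = unname(svp["cc"]),
    svp_pc = unname(svp["pc"]))
}
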