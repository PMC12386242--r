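## Per-hemisegment cell-count records: the tabular unit of scoring.
##
## A record is one hemisegment of one embryo, scored from a confocal z-stack:
## the number of Tinman-expressing cardiac cells (tin_cc), Seven-up cardiac
## cells (svp_cc) and, when the svp-lacZ enhancer-trap reporter is available,
## Seven-up pericardial cells (svp_pc). Two assay modes exist:
##
##  * "svp_lacz":      beta-galactosidase perdurance makes both Svp CCs and
##                     Svp PCs visible, so svp_pc is scored.
##  * "svp_antibody":  the anti-Svp antibody cannot detect the low Svp levels
##                     in the PCs, so svp_pc is structurally missing.

#' Column schema for hemisegment count tables
#'
#' @return character vector of the required column names, in order.
#' @export
record_columns <- function() {
  c("embryo_id", "genotype", "segment", "side",
    "tin_cc", "svp_cc", "svp_pc", "enlarged_svp_nucleus", "assay")
}

#' Valid assay modes
#' @return character vector `c("svp_lacz", "svp_antibody")`.
#' @export
assay_modes <- function() c("svp_lacz", "svp_antibody")

#' Valid abdominal segment names
#' @return character vector `c("A2", ..., "A8")`.
#' @export
segment_names <- function() paste0("A", 2:8)

#' Validate a hemisegment count table
#'
#' Checks the full record contract: required columns, segment names in
#' A2-A8, side in L/R, uniqueness of (embryo_id, segment, side),
#' non-negative integer counts, and assay-dependent handling of `svp_pc`
#' (must be missing in antibody mode, must be a non-negative integer in
#' lacZ mode). Errors name the offending rows.
#'
#' @param records data.frame following [record_columns()].
#' @return the validated data.frame, invisibly, with `segment`, `side` and
#'   `assay` normalised to canonical case.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records)) stop("`records` must be a data.frame")
  if (nrow(records) == 0L) stop("no records: the count table is empty")
  missing_cols <- setdiff(record_columns(), names(records))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(records), record_columns())
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  records <- records[, record_columns()]

  records$segment <- toupper(as.character(records$segment))
  records$side <- toupper(as.character(records$side))
  records$assay <- tolower(as.character(records$assay))
  records$embryo_id <- as.character(records$embryo_id)
  records$genotype <- as.character(records$genotype)

  bad_rows <- function(what, bad) {
    if (any(bad))
      stop(what, " in row(s): ", paste(which(bad), collapse = ", "))
  }
  bad_rows("invalid segment name (expected A2-A8)",
           !records$segment %in% segment_names())
  bad_rows("invalid side (expected L or R)", !records$side %in% c("L", "R"))
  bad_rows("invalid assay (expected svp_lacz or svp_antibody)",
           !records$assay %in% assay_modes())
  bad_rows("tin_cc must be a non-negative integer", !is_count(records$tin_cc))
  bad_rows("svp_cc must be a non-negative integer", !is_count(records$svp_cc))

  lacz <- records$assay == "svp_lacz"
  bad_rows("svp_pc must be a non-negative integer in svp_lacz mode",
           lacz & !is_count(records$svp_pc))
  bad_rows("svp_pc is not scorable in svp_antibody mode and must be missing",
           !lacz & !is.na(records$svp_pc))
  if (!is.logical(records$enlarged_svp_nucleus))
    records$enlarged_svp_nucleus <- as.logical(records$enlarged_svp_nucleus)

  key <- paste(records$embryo_id, records$segment, records$side, sep = "|")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicated (embryo_id, segment, side): ",
         paste(unique(key[dup]), collapse = "; "),
         " (row(s) ", paste(which(dup), collapse = ", "), ")")

  ## genotype and assay must be constant within an embryo
  for (col in c("genotype", "assay")) {
    n_per <- tapply(records[[col]], records$embryo_id,
                    function(x) length(unique(x)))
    if (any(n_per > 1L))
      stop("embryo(s) with inconsistent ", col, ": ",
           paste(names(n_per)[n_per > 1L], collapse = ", "))
  }
  invisible(records)
}

#' Read a hemisegment count table from CSV or TSV
#'
#' Empty cells are read as missing. The file must carry exactly the header
#' of [record_columns()]. Row numbers in error messages refer to data rows
#' (header excluded).
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param assay optional assay mode; when given, every record must match it.
#' @return validated records data.frame.
#' @export
read_counts <- function(path, assay = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("no records in ", path)
  for (col in c("tin_cc", "svp_cc", "svp_pc")) {
    if (!col %in% names(raw)) next
    num <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(num)
    if (any(bad))
      stop("non-numeric ", col, " in row(s): ",
           paste(which(bad), collapse = ", "))
    raw[[col]] <- num
  }
  if ("enlarged_svp_nucleus" %in% names(raw))
    raw$enlarged_svp_nucleus <- as.logical(raw$enlarged_svp_nucleus)
  records <- validate_records(raw)
  if (!is.null(assay)) {
    assay <- match.arg(tolower(assay), assay_modes())
    if (!all(records$assay == assay))
      stop("file contains assay mode(s) other than ", assay)
  }
  records
}

#' Write a hemisegment count table to CSV
#'
#' @param records validated records data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(records, path) {
  records <- validate_records(records)
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
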