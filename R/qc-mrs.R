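#' Cramer-Rao lower bound quality filter
#'
#' Retains metabolite quantification records whose CRLB is strictly below
#' `max_crlb_percent` (the conventional "< 20%" reliability rule). Exclusion
#' is per metabolite record, not per subject.
#'
#' @param records Tibble with at least `crlb_percent` (typically also
#'   `subject_id`, `metabolite`, `concentration`).
#' @param max_crlb_percent Threshold, default 20.
#' @return The retained records; the excluded rows are attached as attribute
#'   `excluded` and reported via a message when any.
#' @export
crlb_filter <- function(records, max_crlb_percent = 20) {
  stopifnot("crlb_percent" %in% names(records))
  keep <- records$crlb_percent < max_crlb_percent
  excluded <- records[!keep, , drop = FALSE]
  if (nrow(excluded) > 0) {
    inform(sprintf("crlb_filter: excluded %d record(s) with CRLB >= %g%%.",
                   nrow(excluded), max_crlb_percent))
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Cerebrospinal-fluid partial-volume correction
#'
#' Rescales metabolite concentrations for the CSF fraction of the spectroscopy
#' voxel: `corrected = concentration / (1 - f_csf)` (metabolites are assumed
#' absent from CSF). This is the visibility-fraction correction only; tissue
#' water-relaxation terms are deliberately not modelled.
#'
#' @param records Tibble with `concentration` and `f_csf` (and optionally
#'   `f_gm`, `f_wm`, whose sum with `f_csf` is sanity-checked to 1 within
#'   0.01).
#' @return `records` with an added `concentration_corrected` column.
#' @export
csf_correct <- function(records) {
  stopifnot(all(c("concentration", "f_csf") %in% names(records)))
  if (any(records$f_csf >= 1)) abort("f_csf must be < 1.")
  if (any(records$f_csf < 0)) abort("f_csf must be non-negative.")
  if (all(c("f_gm", "f_wm") %in% names(records))) {
    tot <- records$f_gm + records$f_wm + records$f_csf
    if (any(abs(tot - 1) >= 0.01)) {
      warn("tissue fractions do not sum to 1 (tolerance 0.01) for some records.")
    }
  }
  records$concentration_corrected <- records$concentration / (1 - records$f_csf)
  records
}
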