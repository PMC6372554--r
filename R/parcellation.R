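#' Cerebrum-only parcellation labels (90 regions)
#'
#' Short region codes for the 90 cerebral regions of the automated anatomical
#' labeling atlas (45 per hemisphere, cerebellum excluded), in the conventional
#' interleaved left/right order. These are the node labels every connectivity
#' matrix and cohort produced by the package carries.
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' length(aal90_labels())
aal90_labels <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  as.vector(rbind(paste0(base, ".L"), paste0(base, ".R")))
}

#' Default module layout of the synthetic cohorts
#'
#' Six functional modules (central, default-mode, frontoparietal, occipital,
#' subcortical, hippocampal) with sizes 18, 20, 17, 14, 10 and 11, summing to
#' the 90 cerebral parcels. The synthetic generator plants this partition in
#' the covariance structure; the assignment of parcels to modules is a fixed
#' contiguous blocking of [aal90_labels()] (the generator's covariance only
#' depends on module sizes, not on which anatomical label lands where).
#'
#' @return Named integer vector: module sizes, named by module.
#' @export
default_module_sizes <- function() {
  c(Central = 18L, DMN = 20L, FP = 17L, Occipital = 14L,
    Subcortical = 10L, Hippocampal = 11L)
}

#' Planted reference partition for the default synthetic configuration
#'
#' @param sizes Named integer vector of module sizes (default
#'   [default_module_sizes()]).
#' @param labels Node labels; default [aal90_labels()] truncated/recycled to
#'   `sum(sizes)` nodes.
#' @return An `fc_partition` (see [detect_modules()]) with module names.
#' @export
planted_partition <- function(sizes = default_module_sizes(),
                              labels = NULL) {
  n <- sum(sizes)
  if (is.null(labels)) {
    labels <- if (n == 90L) aal90_labels() else paste0("R", seq_len(n))
  }
  stopifnot(length(labels) == n)
  membership <- rep(seq_along(sizes), times = sizes)
  names(membership) <- labels
  new_fc_partition(membership, q = NA_real_,
                   module_names = names(sizes))
}
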