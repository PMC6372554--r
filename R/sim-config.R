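#' Synthetic cohort configuration
#'
#' Parameters of the synthetic two-group cohort generator. `n_patients` and
#' `n_controls` are the post-QC target sizes; the generator recruits
#' additional subjects planted to fail quality control (`motion_outliers` per
#' group, `crlb_outliers` patients with unusable spectroscopy), so the default
#' recruited pool is 24 patients and 29 controls, of which 20 and 26 survive
#' the default filters.
#'
#' The correlation structure plants six modules (sizes 18, 20, 17, 14, 10,
#' 11). Patients receive additive deltas on specific module couplings:
#' -0.15 on FP-Central and FP-Hippocampal coupling and +0.15 on FP
#' intra-module coupling. Each subject additionally gets a small random
#' deviation (`fc_between_sd`) on the FP-Central and FP-Hippocampal
#' couplings; the control-group metabolite and the patient clinical scores
#' couple to these per-subject planted values.
#'
#' @param n_patients,n_controls Post-QC group sizes (defaults 20 and 26).
#' @param n_timepoints Retained volumes per subject (default 230 = 240 minus
#'   10 discarded; the emitted series are already trimmed).
#' @param module_sizes Named integer vector; must sum to the region count.
#' @param r_intra Within-module correlation (scalar or one per module).
#' @param r_inter Baseline between-module correlation.
#' @param effect_map Tibble (`group`, `module_a`, `module_b`, `delta`) of
#'   additive coupling deltas; `module_a == module_b` targets the intra-module
#'   block.
#' @param fc_between_sd SD of the per-subject coupling deviation on the focal
#'   module pairs (FP-Central, FP-Hippocampal).
#' @param coupling_slope Institutional units of the coupled metabolite per
#'   unit of planted FP-Central coupling, control group only (patients are
#'   decoupled: slope 0).
#' @param coupling_noise_sd Metabolite observation noise SD.
#' @param coupling_metabolite Which metabolite couples (default `"NAA"`).
#' @param clinical_coupling Strength (0-1) of the monotone link from the
#'   planted FP-Central (negative) and FP-Hippocampal (positive) couplings to
#'   the PANSS general/total scores of patients.
#' @param obs_noise_sd White observation noise added on top of the correlated
#'   signal (unit-variance scale).
#' @param motion_outliers Planted motion outliers per group (default 3: one
#'   translation spike, one rotation spike, one high-frequency mean-FD
#'   outlier).
#' @param crlb_outliers Patients planted with CRLB >= 20% on all metabolites
#'   (default 1).
#' @param tr_s Repetition time in seconds.
#' @param seed Integer seed; the entire cohort is a deterministic function of
#'   it.
#' @return A `fc_sim_config` list, validated.
#' @export
fc_sim_config <- function(n_patients = 20, n_controls = 26,
                          n_timepoints = 230,
                          module_sizes = default_module_sizes(),
                          r_intra = 0.5, r_inter = 0.1,
                          effect_map = default_effect_map(),
                          fc_between_sd = 0.08,
                          coupling_slope = 25, coupling_noise_sd = 1.0,
                          coupling_metabolite = "NAA",
                          clinical_coupling = 0.65,
                          obs_noise_sd = 0.2,
                          motion_outliers = 3, crlb_outliers = 1,
                          tr_s = 2, seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_regions = sum(module_sizes), n_timepoints = as.integer(n_timepoints),
    module_sizes = module_sizes, r_intra = r_intra, r_inter = r_inter,
    effect_map = effect_map, fc_between_sd = fc_between_sd,
    coupling_slope = coupling_slope, coupling_noise_sd = coupling_noise_sd,
    coupling_metabolite = coupling_metabolite,
    clinical_coupling = clinical_coupling,
    obs_noise_sd = obs_noise_sd,
    motion_outliers = as.integer(motion_outliers),
    crlb_outliers = as.integer(crlb_outliers),
    tr_s = tr_s, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "fc_sim_config")
}

#' @rdname fc_sim_config
#' @export
default_effect_map <- function() {
  tibble(
    group = "patient",
    module_a = c("FP", "FP", "FP"),
    module_b = c("Central", "Hippocampal", "FP"),
    delta = c(-0.15, -0.15, 0.15)
  )
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1 || cfg$n_controls < 1) abort("group sizes must be positive.")
  if (cfg$n_timepoints < 4) abort("n_timepoints too small.")
  if (is.null(names(cfg$module_sizes))) abort("module_sizes must be named.")
  if (any(cfg$module_sizes < 1)) abort("module sizes must be positive.")
  r_i <- cfg$r_intra
  if (!(length(r_i) %in% c(1, length(cfg$module_sizes)))) {
    abort("r_intra must be scalar or one value per module.")
  }
  if (!(cfg$r_inter >= 0 && all(cfg$r_inter < r_i) && all(r_i < 1))) {
    abort("need 0 <= r_inter < r_intra < 1.")
  }
  if (cfg$motion_outliers < 0 || cfg$crlb_outliers < 0) abort("outlier counts must be >= 0.")
  if (cfg$obs_noise_sd < 0 || cfg$fc_between_sd < 0) abort("noise SDs must be >= 0.")
  invisible(cfg)
}
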