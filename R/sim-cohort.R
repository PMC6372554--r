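# focal module pairs the couplings attach to: FP-Central and FP-Hippocampal
# when those names exist, otherwise the first available pairs.
focal_pairs <- function(module_names) {
  if (all(c("FP", "Central", "Hippocampal") %in% module_names)) {
    list(c("FP", "Central"), c("FP", "Hippocampal"))
  } else {
    n <- length(module_names)
    p1 <- module_names[c(1, min(2, n))]
    p2 <- module_names[c(1, n)]
    list(p1, p2)
  }
}

# smooth bounded motion trace: stationary AR(1) per parameter
ou_trace <- function(n_t, sd_trans, sd_rot, phi = 0.95) {
  one <- function(s) {
    x <- numeric(n_t)
    x[1] <- rnorm(1, 0, s)
    innov_sd <- s * sqrt(1 - phi^2)
    for (t in 2:n_t) x[t] <- phi * x[t - 1] + rnorm(1, 0, innov_sd)
    x
  }
  m <- cbind(one(sd_trans), one(sd_trans), one(sd_trans),
             one(sd_rot), one(sd_rot), one(sd_rot))
  colnames(m) <- motion_cols
  m
}

simulate_motion <- function(n_t, outlier_type = "none",
                            base_trans = 0.15, base_rot = 0.15) {
  amp <- runif(1, 0.8, 1.2)
  m <- ou_trace(n_t, base_trans * amp, base_rot * amp)
  half <- floor(n_t / 2)
  if (outlier_type == "translation") {
    m[(half + 1):n_t, "trans_x_mm"] <- m[(half + 1):n_t, "trans_x_mm"] + 3.2
  } else if (outlier_type == "rotation") {
    m[(half + 1):n_t, "rot_x_deg"] <- m[(half + 1):n_t, "rot_x_deg"] + 3.2
  } else if (outlier_type == "fd") {
    m[, 1:3] <- m[, 1:3] + matrix(rnorm(n_t * 3, sd = 0.11), n_t, 3)
  }
  m
}

#' Generate a synthetic two-group cohort
#'
#' Draws every subject's regional time series from a zero-mean multivariate
#' normal whose correlation matrix carries the planted modular structure (see
#' [planted_covariance()]), plus white observation noise. Patients receive the
#' configured coupling deltas; every subject additionally receives a small
#' random deviation on the FP-Central and FP-Hippocampal couplings, and these
#' per-subject planted values drive the control-group metabolite coupling and
#' the patient clinical-score coupling. Motion traces are smooth bounded
#' AR(1) walks; the planted outliers get a translation spike, a rotation
#' spike, or high-frequency jitter (mean-FD outlier). One patient (by
#' default) gets CRLB >= 20% on all metabolite records, emulating unusable
#' spectroscopy.
#'
#' All randomness flows from `config$seed`: the same seed reproduces the
#' cohort bit for bit.
#'
#' @param config A [fc_sim_config()].
#' @return An `fc_cohort`: list with `subjects` (tibble with list-columns
#'   `ts`, `motion`), `metabolites`, `clinical`, `partition` (planted),
#'   `region_labels`, and the `config` echo.
#' @export
generate_cohort <- function(config = fc_sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  part <- planted_partition(config$module_sizes)
  mod_names <- part$module_names
  pairs <- focal_pairs(mod_names)
  n_rec <- c(
    patient = config$n_patients + config$motion_outliers + config$crlb_outliers,
    control = config$n_controls + config$motion_outliers
  )
  subjects <- list()
  metab_rows <- list()
  clin_rows <- list()
  metab_means <- c(NAA = 12, `GABA+` = 2.5, Glx = 10)
  metab_sds <- c(NAA = 0, `GABA+` = 0.4, Glx = 1.2)  # NAA noise handled via coupling
  for (grp in c("patient", "control")) {
    n_g <- n_rec[[grp]]
    grp_deltas <- if (!is.null(config$effect_map)) {
      config$effect_map[config$effect_map$group == grp, , drop = FALSE]
    } else NULL
    # planted-to-fail subjects sit at the end of the recruited order
    outlier_type <- rep("none", n_g)
    mo <- config$motion_outliers
    if (mo > 0) {
      types <- rep(c("translation", "rotation", "fd"), length.out = mo)
      outlier_type[(n_g - mo + 1):n_g] <- types
    }
    if (grp == "patient" && config$crlb_outliers > 0) {
      crlb_idx <- (n_g - mo - config$crlb_outliers + 1):(n_g - mo)
      outlier_type[crlb_idx] <- "crlb"
    }
    for (i in seq_len(n_g)) {
      sid <- sprintf("%s%02d", if (grp == "patient") "P" else "C", i)
      jit <- c(rnorm(1, 0, config$fc_between_sd),
               rnorm(1, 0, config$fc_between_sd))
      jit <- pmin(pmax(jit, -2.4 * config$fc_between_sd),
                  2.4 * config$fc_between_sd)
      jitter_tbl <- tibble(
        module_a = c(pairs[[1]][1], pairs[[2]][1]),
        module_b = c(pairs[[1]][2], pairs[[2]][2]),
        delta = jit
      )
      deltas <- if (is.null(grp_deltas)) jitter_tbl else
        dplyr::bind_rows(grp_deltas[, c("module_a", "module_b", "delta")],
                         jitter_tbl)
      sigma <- suppressMessages(
        planted_covariance(part, config$r_intra, config$r_inter, deltas)
      )
      blk <- function(pair) {
        ia <- part$membership == resolve_module(part, pair[1])
        ib <- part$membership == resolve_module(part, pair[2])
        mean(sigma[ia, ib])
      }
      fpc <- blk(pairs[[1]])
      fph <- blk(pairs[[2]])
      ts <- rmvn_ts(config$n_timepoints, sigma, config$obs_noise_sd)
      motion <- simulate_motion(
        config$n_timepoints,
        if (outlier_type[i] %in% c("translation", "rotation", "fd"))
          outlier_type[i] else "none"
      )
      subjects[[length(subjects) + 1]] <- tibble(
        subject_id = sid, group = grp,
        ts = list(ts), motion = list(motion),
        planted_outlier = outlier_type[i],
        planted_fpc = fpc, planted_fph = fph,
        sigma_repaired = isTRUE(attr(sigma, "repaired")),
        sigma_repair_frobenius = attr(sigma, "frobenius_repair") %||% 0
      )
      # metabolites: coupling acts on the control group only
      crlb_bad <- outlier_type[i] == "crlb"
      for (met in names(metab_means)) {
        conc <- metab_means[[met]] + rnorm(1, 0, metab_sds[[met]])
        if (met == config$coupling_metabolite) {
          slope <- if (grp == "control") config$coupling_slope else 0
          conc <- metab_means[[met]] +
            slope * (fpc - config$r_inter) +
            rnorm(1, 0, config$coupling_noise_sd)
        }
        f_gm <- runif(1, 0.5, 0.6)
        f_csf <- runif(1, 0.05, 0.2)
        metab_rows[[length(metab_rows) + 1]] <- tibble(
          subject_id = sid, group = grp, metabolite = met,
          concentration = conc,
          crlb_percent = if (crlb_bad) runif(1, 25, 60) else runif(1, 3, 15),
          f_gm = f_gm, f_wm = 1 - f_gm - f_csf, f_csf = f_csf
        )
      }
      if (grp == "patient") {
        clin_rows[[length(clin_rows) + 1]] <- tibble(
          subject_id = sid, planted_fpc = fpc, planted_fph = fph
        )
      }
    }
  }
  subjects <- dplyr::bind_rows(subjects)
  metabolites <- dplyr::bind_rows(metab_rows)
  clinical <- make_clinical(dplyr::bind_rows(clin_rows),
                            config$clinical_coupling)
  structure(
    list(
      subjects = subjects,
      metabolites = metabolites,
      clinical = clinical,
      partition = part,
      region_labels = names(part$membership),
      config = config
    ),
    class = "fc_cohort"
  )
}

# monotone link of patient symptom scores to planted couplings:
# general/total decrease with FP-Central coupling, increase with FP-Hippocampal
make_clinical <- function(planted, a) {
  n <- nrow(planted)
  if (n == 0) {
    return(tibble(subject_id = character(), panss_pos = numeric(),
                  panss_neg = numeric(), panss_gen = numeric(),
                  panss_total = numeric(), cgi = numeric()))
  }
  std <- function(x) {
    s <- sd(x)
    if (length(x) >= 2 && is.finite(s) && s > 0) (x - mean(x)) / s else x * 0
  }
  zc <- std(planted$planted_fpc)
  zh <- std(planted$planted_fph)
  noise_sd <- sqrt(max(0, 1 - 2 * a^2))
  u <- -a * zc + a * zh + rnorm(n, 0, noise_sd)
  pos <- pmax(7, round(22.4 + 5.8 * rnorm(n)))
  neg <- pmax(7, round(20.2 + 5.9 * rnorm(n)))
  gen <- pmax(16, round(39.2 + 5.3 * u))
  tibble(
    subject_id = planted$subject_id,
    panss_pos = pos, panss_neg = neg, panss_gen = gen,
    panss_total = pos + neg + gen,
    cgi = pmin(7, pmax(1, round(5 + 0.88 * rnorm(n))))
  )
}

#' @export
print.fc_cohort <- function(x, ...) {
  tb <- table(x$subjects$group)
  cat(sprintf("<fc_cohort> %d subjects (%s), %d regions x %d timepoints\n",
              nrow(x$subjects),
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", "),
              length(x$region_labels), x$config$n_timepoints))
  cat(sprintf("  planted outliers: %s\n",
              paste(x$subjects$subject_id[x$subjects$planted_outlier != "none"],
                    collapse = " ")))
  invisible(x)
}
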