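#' Condition one subject's regional series
#'
#' Nuisance regression on the Friston-24 motion design, followed by linear
#' detrending and 0.01-0.1 Hz band-pass filtering. A global-signal regressor
#' (the mean over all regions, a region-space proxy for image-space global
#' signal regression) is available but off by default: removing the global
#' mean re-centers between-module correlations around zero, which discards
#' the positive between-module coupling that one-sided edge retention and the
#' inter-module connectivity statistics are built on. See the methods
#' vignette for the full reasoning.
#'
#' @param ts T x N regional series.
#' @param motion T x 6 motion trace.
#' @param tr_s Repetition time (s).
#' @param low_hz,high_hz Pass band.
#' @param global_signal Also regress the mean regional signal (default
#'   `FALSE`).
#' @return Cleaned T x N matrix.
#' @export
preprocess_subject <- function(ts, motion, tr_s = 2, low_hz = 0.01,
                               high_hz = 0.1, global_signal = FALSE) {
  reg <- friston24(motion)
  if (global_signal) reg <- cbind(reg, global_signal = rowMeans(ts))
  res <- nuisance_regress(ts, reg)
  detrend_bandpass(res, tr_s = tr_s, low_hz = low_hz, high_hz = high_hz)
}

#' Cohort-level quality control
#'
#' Combines the motion rules ([motion_exclusion()]) with a spectroscopy
#' completeness rule: a subject with no metabolite record passing the CRLB
#' filter has unusable MRS and is excluded from the final sample.
#'
#' @param cohort An `fc_cohort`.
#' @param max_trans_mm,max_rot_deg,fd_sd_mult Motion rules.
#' @param max_crlb_percent CRLB threshold.
#' @return QC report tibble (one row per recruited subject) with `included`
#'   and `reason`.
#' @export
qc_cohort <- function(cohort, max_trans_mm = 2.5, max_rot_deg = 2.5,
                      fd_sd_mult = 2, max_crlb_percent = 20) {
  motion_rep <- motion_exclusion(
    cohort$subjects[, c("subject_id", "group", "motion")],
    max_trans_mm = max_trans_mm, max_rot_deg = max_rot_deg,
    fd_sd_mult = fd_sd_mult
  )
  retained <- suppressMessages(crlb_filter(cohort$metabolites, max_crlb_percent))
  has_mrs <- cohort$subjects$subject_id %in% unique(retained$subject_id)
  mrs_fail <- !has_mrs
  out <- motion_rep
  out$crlb_fail <- mrs_fail[match(out$subject_id, cohort$subjects$subject_id)]
  out$reason <- ifelse(!out$included, out$reason,
                       ifelse(out$crlb_fail, "incomplete_mrs", NA_character_))
  out$included <- out$included & !out$crlb_fail
  out
}

#' Run the full modular functional-metabolic coupling analysis
#'
#' End-to-end orchestration: quality control, per-subject signal conditioning,
#' Fisher-z connectivity, group-level edge-wise FDR retention, connectedness-
#' based sparsity selection, greedy modular detection on each group-average
#' network, per-subject intra/inter-module connectivity under the
#' control-group partition, group t-tests on the frontoparietal contrasts,
#' Pearson correlation of the corrected coupling metabolite with FP-Central
#' connectivity per group, and Spearman correlations of module metrics with
#' patient symptom scores. Grubbs outlier screening precedes every
#' correlation.
#'
#' @param cohort An `fc_cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param q Edge-wise FDR level (default 0.05).
#' @param sparsity `"auto"` (connectedness-based selection over 0.05-0.30) or
#'   a numeric value.
#' @param welch Welch t-test for group contrasts (default `TRUE`).
#' @param max_crlb_percent CRLB quality threshold.
#' @param outlier_screen Apply Grubbs screening before correlations.
#' @param global_signal Include the region-mean global-signal regressor in
#'   subject preprocessing (default `FALSE`; see [preprocess_subject()]).
#' @param metrics_mask Edge mask for the subject-level module metrics:
#'   `"fdr"` (default) uses the subject's group FDR mask, so every retained
#'   edge contributes to the intra/inter-module means; `"fdr_sparsity"`
#'   additionally restricts to the group-average sparsity mask used for module
#'   detection (top-edge selection can leave whole between-module blocks with
#'   no surviving edges, so this mode is degenerate-prone; see the vignette).
#' @return An `fc_analysis` list: `qc`, `selected_sparsity`, `sparsity_table`,
#'   `partitions` (per group, control named by planted overlap when
#'   available), `metrics`, `group_tests`, `metabolite_correlations`,
#'   `clinical_correlations`, `provenance`.
#' @export
run_full_analysis <- function(cohort, q = 0.05, sparsity = "auto",
                              welch = TRUE, max_crlb_percent = 20,
                              outlier_screen = TRUE, global_signal = FALSE,
                              metrics_mask = c("fdr", "fdr_sparsity")) {
  metrics_mask <- match.arg(metrics_mask)
  qc <- qc_cohort(cohort, max_crlb_percent = max_crlb_percent)
  keep_ids <- qc$subject_id[qc$included]
  subj <- cohort$subjects[cohort$subjects$subject_id %in% keep_ids, ]

  z_mats <- purrr::map2(subj$ts, subj$motion, function(ts, mo) {
    correlation_matrix(
      preprocess_subject(ts, mo, tr_s = cohort$config$tr_s %||% 2,
                         global_signal = global_signal),
      fisher = TRUE
    )
  })
  names(z_mats) <- subj$subject_id

  groups <- c("control", "patient")
  fdr_masks <- list()
  masked_mats <- vector("list", nrow(subj))
  for (g in groups) {
    idx <- which(subj$group == g)
    fdr_masks[[g]] <- edgewise_fdr_mask(z_mats[idx], q = q)
    for (i in idx) {
      masked_mats[[i]] <- new_fc_matrix(
        unclass(z_mats[[i]]) * unclass(fdr_masks[[g]]), "z")
    }
  }
  names(masked_mats) <- subj$subject_id

  if (identical(sparsity, "auto")) {
    sel <- select_sparsity(masked_mats)
  } else {
    sel <- list(selected = as.numeric(sparsity), all_connected = NA,
                table = tibble(sparsity = as.numeric(sparsity),
                               n_connected = NA_integer_, selected = TRUE))
  }

  partitions <- list()
  metric_masks <- list()
  group_avgs <- list()
  group_avgs_full <- list()
  for (g in groups) {
    idx <- which(subj$group == g)
    avg <- group_average(z_mats[idx], fdr_masks[[g]])
    sp_mask <- sparsity_threshold(avg, sel$selected)
    metric_masks[[g]] <- if (metrics_mask == "fdr") fdr_masks[[g]] else
      mask_intersect(fdr_masks[[g]], sp_mask)
    group_avgs_full[[g]] <- avg
    group_avgs[[g]] <- new_fc_matrix(unclass(avg) * unclass(sp_mask), "z")
    partitions[[g]] <- suppressWarnings(detect_modules(group_avgs[[g]]))
  }
  if (!is.null(cohort$partition) && !is.null(cohort$partition$module_names)) {
    partitions$control <- name_modules_by_overlap(partitions$control,
                                                  cohort$partition)
  }
  ref_part <- partitions$control

  metrics <- purrr::pmap(
    list(subj$subject_id, subj$group, seq_len(nrow(subj))),
    function(sid, g, i) {
      subject_module_metrics(z_mats[[i]], metric_masks[[g]], ref_part,
                             subject_id = sid, group = g)
    }
  ) |> dplyr::bind_rows()
  metrics <- canonicalize_fp_metrics(metrics)

  fp_contrasts <- c("intra_FP", "inter_FP_Central", "inter_FP_Hippocampal")
  have <- intersect(unique(metrics$metric), fp_contrasts)
  group_tests <- purrr::map(have, function(mn) {
    a <- metrics$value[metrics$metric == mn & metrics$group == "patient"]
    b <- metrics$value[metrics$metric == mn & metrics$group == "control"]
    res <- tryCatch(tidy(two_sample_ttest(a, b, welch = welch)),
                    error = function(e) {
                      tibble(method = "welch_ttest",
                             estimate = mean(a) - mean(b),
                             statistic = NA_real_, df = NA_real_,
                             p.value = NA_real_,
                             n = paste(length(a), length(b), sep = ","),
                             flags = "degenerate")
                    })
    dplyr::bind_cols(tibble(contrast = mn, group = "patient_vs_control"), res)
  }) |> dplyr::bind_rows()

  # metabolite coupling: CRLB filter, CSF correction, per-group Pearson
  met <- suppressMessages(crlb_filter(cohort$metabolites, max_crlb_percent))
  met <- csf_correct(met)
  coupling_met <- cohort$config$coupling_metabolite %||% "NAA"
  coupling_metric <- if ("inter_FP_Central" %in% metrics$metric)
    "inter_FP_Central" else unique(metrics$metric)[1]
  metab_cors <- purrr::map(groups, function(g) {
    run_screened_corr(
      metrics, met, g, coupling_metric, coupling_met,
      screen = outlier_screen
    )
  }) |> dplyr::bind_rows()

  clin_cors <- clinical_correlations(metrics, cohort$clinical,
                                     screen = outlier_screen)

  structure(
    list(
      qc = qc,
      selected_sparsity = sel$selected,
      sparsity_all_connected = sel$all_connected,
      sparsity_table = sel$table,
      fdr_masks = fdr_masks,
      metric_masks = metric_masks,
      group_networks = group_avgs,
      group_averages = group_avgs_full,
      partitions = partitions,
      metrics = metrics,
      group_tests = group_tests,
      metabolite_correlations = metab_cors,
      clinical_correlations = clin_cors,
      provenance = list(
        seed = cohort$config$seed %||% NA_integer_,
        q = q, sparsity = sparsity, welch = welch,
        max_crlb_percent = max_crlb_percent,
        package_version = as.character(utils::packageVersion("fcmodular"))
      )
    ),
    class = "fc_analysis"
  )
}

# metric names come out of subject_module_metrics() in module-id order;
# put FP first in inter-module names so the frontoparietal contrasts have
# stable names regardless of detection order.
canonicalize_fp_metrics <- function(metrics) {
  swap <- !is.na(metrics$module_b) & metrics$module_b == "FP" &
    metrics$module_a != "FP" & grepl("^inter_", metrics$metric)
  if (any(swap)) {
    a <- metrics$module_a[swap]
    metrics$module_a[swap] <- "FP"
    metrics$module_b[swap] <- a
    metrics$metric[swap] <- paste0("inter_FP_", a)
  }
  metrics
}

# Pearson of a module metric vs a corrected metabolite within one group,
# with optional Grubbs screening on both variables (union of flags removed).
run_screened_corr <- function(metrics, met, g, metric_name, metabolite,
                              screen = TRUE) {
  mt <- metrics[metrics$metric == metric_name & metrics$group == g, ]
  mm <- met[met$metabolite == metabolite & met$group == g, ]
  merged <- dplyr::inner_join(
    mt[, c("subject_id", "value")],
    mm[, c("subject_id", "concentration_corrected")],
    by = "subject_id"
  )
  n_removed <- 0L
  x <- merged$value
  y <- merged$concentration_corrected
  if (screen && nrow(merged) >= 10 && sd(x) > 0 && sd(y) > 0) {
    fx <- detect_outliers(x)$flags
    fy <- detect_outliers(y)$flags
    drop <- fx | fy
    n_removed <- sum(drop)
    x <- x[!drop]; y <- y[!drop]
  }
  res <- tryCatch(tidy(pearson_corr(x, y)), error = function(e) {
    tibble(method = "pearson", estimate = NA_real_, statistic = NA_real_,
           df = length(x) - 2, p.value = NA_real_,
           n = as.character(length(x)), flags = "constant")
  })
  dplyr::bind_cols(
    tibble(contrast = paste0(metric_name, "_vs_", metabolite), group = g,
           outliers_removed = n_removed),
    res
  )
}

# Spearman correlations of FP metrics with patient symptom scores.
clinical_correlations <- function(metrics, clinical, screen = TRUE) {
  if (is.null(clinical) || nrow(clinical) == 0) {
    return(tibble())
  }
  metric_names <- intersect(
    c("intra_FP", "inter_FP_Central", "inter_FP_Hippocampal"),
    unique(metrics$metric)
  )
  scores <- c("panss_gen", "panss_total")
  out <- list()
  for (mn in metric_names) {
    mt <- metrics[metrics$metric == mn & metrics$group == "patient", ]
    merged <- dplyr::inner_join(mt[, c("subject_id", "value")], clinical,
                                by = "subject_id")
    for (sc in scores) {
      x <- merged$value
      y <- merged[[sc]]
      n_removed <- 0L
      if (screen && length(x) >= 10 && sd(x) > 0 && sd(y) > 0) {
        drop <- detect_outliers(x)$flags | detect_outliers(y)$flags
        n_removed <- sum(drop)
        x <- x[!drop]; y <- y[!drop]
      }
      res <- tryCatch(tidy(spearman_corr(x, y)), error = function(e) {
        tibble(method = "spearman", estimate = NA_real_, statistic = NA_real_,
               df = length(x) - 2, p.value = NA_real_,
               n = as.character(length(x)), flags = "constant")
      })
      out[[length(out) + 1]] <- dplyr::bind_cols(
        tibble(contrast = paste0(mn, "_vs_", sc), group = "patient",
               outliers_removed = n_removed),
        res
      )
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.fc_analysis <- function(x, ...) {
  inc <- table(x$qc$group[x$qc$included])
  cat(sprintf("<fc_analysis> %s included; sparsity %.2f; control Q^W = %.3f (%d modules)\n",
              paste(sprintf("%d %s", inc, names(inc)), collapse = ", "),
              x$selected_sparsity, x$partitions$control$Q,
              x$partitions$control$n_modules))
  invisible(x)
}

#' @export
tidy.fc_analysis <- function(x, ...) {
  dplyr::bind_rows(
    x$group_tests,
    x$metabolite_correlations,
    x$clinical_correlations
  )
}

#' @export
glance.fc_analysis <- function(x, ...) {
  tibble(
    n_included = sum(x$qc$included),
    n_patients = sum(x$qc$included & x$qc$group == "patient"),
    n_controls = sum(x$qc$included & x$qc$group == "control"),
    selected_sparsity = x$selected_sparsity,
    q_control = x$partitions$control$Q,
    q_patient = x$partitions$patient$Q,
    modules_control = x$partitions$control$n_modules,
    modules_patient = x$partitions$patient$n_modules
  )
}

#' Write a machine-readable analysis report
#'
#' Emits `report.json` (QC, sparsity selection, partitions, all statistics,
#' provenance), a flat `stats.csv`, and `metrics.csv`.
#'
#' @param analysis An `fc_analysis`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stats <- tidy(analysis)
  readr::write_csv(stats, file.path(dir, "stats.csv"))
  readr::write_csv(analysis$metrics, file.path(dir, "metrics.csv"))
  part_json <- function(p) list(
    nodes = names(p$membership), module_of = unname(p$membership),
    Q = p$Q, module_names = p$module_names
  )
  report <- list(
    schema = "fcmodular-report-v1",
    provenance = analysis$provenance,
    qc = analysis$qc,
    selected_sparsity = analysis$selected_sparsity,
    sparsity_table = analysis$sparsity_table,
    partitions = lapply(analysis$partitions, part_json),
    stats = stats
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
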