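#' Write a cohort to a directory of plain-text files
#'
#' Layout: `manifest.json` (group labels, file paths, seed, config echo,
#' planted partition), one `*_timeseries.tsv` per subject (T rows, region
#' labels as header), one `*_motion.tsv` per subject (T x 6, standard motion
#' header), `metabolites.csv` and `clinical.csv`.
#'
#' @param cohort An `fc_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj_entries <- purrr::pmap(
    list(cohort$subjects$subject_id, cohort$subjects$group,
         cohort$subjects$ts, cohort$subjects$motion,
         cohort$subjects$planted_outlier),
    function(sid, grp, ts, motion, outlier) {
      ts_file <- paste0(sid, "_timeseries.tsv")
      mo_file <- paste0(sid, "_motion.tsv")
      readr::write_tsv(as_tibble(as.data.frame(ts)), file.path(dir, ts_file))
      readr::write_tsv(as_tibble(as.data.frame(motion)), file.path(dir, mo_file))
      list(subject_id = sid, group = grp, timeseries = ts_file,
           motion = mo_file, planted_outlier = outlier)
    }
  )
  readr::write_csv(cohort$metabolites, file.path(dir, "metabolites.csv"))
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  cfg <- unclass(cohort$config)
  cfg$effect_map <- if (!is.null(cfg$effect_map)) as.data.frame(cfg$effect_map)
  manifest <- list(
    format = "fcmodular-cohort-v1",
    seed = cohort$config$seed,
    volumes_discarded_already = 10,
    motion_rows = "equal to timeseries rows",
    region_labels = cohort$region_labels,
    module_names = cohort$partition$module_names,
    planted_partition = unname(cohort$partition$membership),
    config = cfg,
    subjects = subj_entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write / read a labeled square matrix as TSV
#'
#' Plain-text exchange format for connectivity matrices and masks: N rows by
#' N columns with region labels as header and first column.
#'
#' @param m Square matrix with dimnames (an [fc_matrix()]/[fc_mask()] or
#'   plain matrix).
#' @param path File path.
#' @return `write_matrix_tsv()`: `path`, invisibly. `read_matrix_tsv()`: a
#'   plain labeled matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(unclass(m))
  df <- cbind(region = rownames(m) %||% paste0("R", seq_len(nrow(m))), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(labels, colnames(m))
  m
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return An `fc_cohort` (planted per-subject coupling values are not stored
#'   on disk and come back as `NA`; the planted partition and outlier flags
#'   are restored from the manifest).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  labels <- manifest$region_labels
  subj <- manifest$subjects
  rows <- purrr::pmap(
    list(subj$subject_id, subj$group, subj$timeseries, subj$motion,
         subj$planted_outlier),
    function(sid, grp, ts_file, mo_file, outlier) {
      ts <- as.matrix(readr::read_tsv(file.path(dir, ts_file),
                                      show_col_types = FALSE))
      mo <- as.matrix(readr::read_tsv(file.path(dir, mo_file),
                                      show_col_types = FALSE))
      tibble(subject_id = sid, group = grp, ts = list(ts), motion = list(mo),
             planted_outlier = outlier,
             planted_fpc = NA_real_, planted_fph = NA_real_)
    }
  )
  membership <- setNames(as.integer(manifest$planted_partition), labels)
  part <- new_fc_partition(membership, module_names = manifest$module_names)
  cfg <- manifest$config
  cfg$module_sizes <- setNames(as.integer(unlist(cfg$module_sizes)),
                               names(cfg$module_sizes) %||% manifest$module_names)
  if (!is.null(cfg$effect_map)) cfg$effect_map <- as_tibble(cfg$effect_map)
  structure(
    list(
      subjects = dplyr::bind_rows(rows),
      metabolites = readr::read_csv(file.path(dir, "metabolites.csv"),
                                    show_col_types = FALSE),
      clinical = readr::read_csv(file.path(dir, "clinical.csv"),
                                 show_col_types = FALSE),
      partition = part,
      region_labels = labels,
      config = structure(cfg, class = "fc_sim_config")
    ),
    class = "fc_cohort"
  )
}
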