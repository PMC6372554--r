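#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_boxplot geom_jitter geom_smooth scale_fill_gradient2 labs
#'   theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Heatmap of a connectivity matrix
#'
#' @param object An [fc_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  labels <- rownames(object) %||% paste0("R", seq_len(nrow(object)))
  df <- as_tibble(as.data.frame(as.table(unclass(object))),
                  .name_repair = ~c("row", "col", "weight"))
  df$row <- factor(df$row, levels = labels)
  df$col <- factor(df$col, levels = rev(labels))
  ggplot(df, aes(x = .data$row, y = .data$col, fill = .data$weight)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL,
         fill = if (identical(attr(object, "fc_type"), "z")) "Fisher z" else "r") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Modularity across the sparsity grid
#'
#' @param object An `fc_sweep` from [sparsity_sweep()].
#' @param ... Unused.
#' @return A ggplot of Q against sparsity.
#' @export
autoplot.fc_sweep <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$sparsity, y = .data$Q)) +
    geom_line() +
    geom_point(aes(size = .data$n_modules), alpha = 0.7) +
    labs(x = "Sparsity", y = expression(Q^W), size = "Modules") +
    theme_minimal()
}

#' Group comparison of module-level connectivity
#'
#' Boxplots of per-subject intra/inter-module connectivity by group for the
#' chosen metrics (defaults: the frontoparietal contrasts).
#'
#' @param metrics Metrics tibble from [subject_module_metrics()] /
#'   [run_full_analysis()].
#' @param which Character vector of metric names.
#' @return A ggplot.
#' @export
plot_module_metrics <- function(metrics,
                                which = c("intra_FP", "inter_FP_Central",
                                          "inter_FP_Hippocampal")) {
  df <- metrics[metrics$metric %in% which, ]
  ggplot(df, aes(x = .data$group, y = .data$value, fill = .data$group)) +
    geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    geom_jitter(width = 0.15, size = 1, alpha = 0.6) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = "Connectivity (Fisher z)") +
    theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Metabolite-connectivity coupling scatter
#'
#' Per-group scatter of a module-level connectivity metric against a
#' (CSF-corrected) metabolite concentration, with a least-squares line — the
#' coupling/decoupling picture.
#'
#' @param metrics Metrics tibble.
#' @param metabolites Metabolite tibble with `concentration_corrected` (see
#'   [csf_correct()]).
#' @param metric_name,metabolite Which metric and metabolite to pair.
#' @return A ggplot faceted by group.
#' @export
plot_coupling <- function(metrics, metabolites,
                          metric_name = "inter_FP_Central",
                          metabolite = "NAA") {
  mt <- metrics[metrics$metric == metric_name, ]
  mm <- metabolites[metabolites$metabolite == metabolite, ]
  df <- dplyr::inner_join(mt[, c("subject_id", "group", "value")],
                          mm[, c("subject_id", "concentration_corrected")],
                          by = "subject_id")
  ggplot(df, aes(x = .data$value, y = .data$concentration_corrected)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = TRUE, linewidth = 0.6) +
    facet_wrap(~group, scales = "free_x") +
    labs(x = paste(metric_name, "(Fisher z)"),
         y = paste(metabolite, "(corrected, i.u.)")) +
    theme_minimal()
}
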