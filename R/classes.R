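# Lightweight S3 containers shared across the pipeline.

new_fc_matrix <- function(w, type = c("z", "r"), extra = list()) {
  type <- match.arg(type)
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  structure(w, class = c("fc_matrix", class(w)), fc_type = type)
}

#' Validate and tag a connectivity matrix
#'
#' @param w Square symmetric numeric matrix with zero diagonal; `dimnames`
#'   carry the region labels.
#' @param type `"r"` for raw Pearson correlations, `"z"` for Fisher-z weights.
#' @return An `fc_matrix` object (a plain matrix with a class tag).
#' @export
fc_matrix <- function(w, type = c("z", "r")) {
  type <- match.arg(type)
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    abort("`w` must be a square matrix.")
  }
  if (max(abs(w - t(w))) > 1e-12) abort("`w` must be symmetric (tol 1e-12).")
  if (any(diag(w) != 0)) abort("`w` must have an exactly zero diagonal.")
  if (type == "r" && any(abs(w) > 1)) abort("raw-r entries must lie in [-1, 1].")
  new_fc_matrix(w, type)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d x %d, type = %s\n", nrow(x), ncol(x),
              attr(x, "fc_type")))
  cat(sprintf("  strength range: [%.4g, %.4g], total weight l^W = %.4g\n",
              min(node_strength(x)), max(node_strength(x)), total_weight(x)))
  invisible(x)
}

#' Node strengths and total weight of a connectivity matrix
#'
#' `node_strength()` returns \eqn{k_i^W = \sum_j w_{ij}}; `total_weight()`
#' returns the ordered-pair total \eqn{l^W = \sum_{ij} w_{ij}} (twice the sum
#' over unordered edges), the normalization used by the weighted modularity.
#'
#' @param w Connectivity matrix (square symmetric, zero diagonal).
#' @return Numeric vector of length N / a scalar.
#' @export
node_strength <- function(w) rowSums(unclass(w))

#' @rdname node_strength
#' @export
total_weight <- function(w) sum(unclass(w))

new_fc_mask <- function(m, provenance = "manual") {
  structure(m, class = c("fc_mask", class(m)), provenance = provenance)
}

#' Construct a binary edge mask
#'
#' @param m Square symmetric 0/1 matrix with zero diagonal.
#' @param provenance Character tag recording how the mask was built
#'   (`"fdr"`, `"sparsity"`, `"combined"`, or `"manual"`).
#' @return An `fc_mask` object.
#' @export
fc_mask <- function(m, provenance = "manual") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("`m` must be square.")
  if (!all(m %in% c(0, 1))) abort("mask entries must be 0 or 1.")
  if (any(m != t(m))) abort("mask must be symmetric.")
  if (any(diag(m) != 0)) abort("mask diagonal must be zero.")
  storage.mode(m) <- "double"
  new_fc_mask(m, provenance)
}

#' @export
print.fc_mask <- function(x, ...) {
  cat(sprintf("<fc_mask> %d x %d, %d edges, provenance = %s\n",
              nrow(x), ncol(x), sum(x) / 2, attr(x, "provenance")))
  invisible(x)
}

#' Combine masks by elementwise conjunction
#'
#' @param ... `fc_mask` objects of identical dimension.
#' @return An `fc_mask` with provenance `"combined"`.
#' @export
mask_intersect <- function(...) {
  ms <- list(...)
  out <- Reduce(`*`, lapply(ms, unclass))
  new_fc_mask(out, "combined")
}

new_fc_partition <- function(membership, q = NA_real_, module_names = NULL) {
  stopifnot(is.numeric(membership))
  membership <- setNames(as.integer(membership), names(membership))
  structure(
    list(membership = membership, Q = q, module_names = module_names,
         n_modules = length(unique(membership))),
    class = "fc_partition"
  )
}

#' Number of modules in a partition
#' @param p An `fc_partition`.
#' @return Integer count.
#' @export
n_modules <- function(p) p$n_modules

#' @export
print.fc_partition <- function(x, ...) {
  cat(sprintf("<fc_partition> %d nodes in %d modules, Q^W = %s\n",
              length(x$membership), x$n_modules,
              ifelse(is.na(x$Q), "NA", format(x$Q, digits = 4))))
  if (!is.null(x$module_names)) {
    sz <- table(factor(x$membership, levels = seq_along(x$module_names)))
    cat("  ", paste(sprintf("%s(%d)", x$module_names, sz), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
tidy.fc_partition <- function(x, ...) {
  nm <- names(x$membership) %||% paste0("node", seq_along(x$membership))
  tibble(
    node = nm,
    module = x$membership,
    module_name = if (is.null(x$module_names)) NA_character_
                  else x$module_names[x$membership]
  )
}

#' @export
glance.fc_partition <- function(x, ...) {
  tibble(n_nodes = length(x$membership), n_modules = x$n_modules, Q = x$Q)
}

# shared input check: matrix/mask/partition dimensions agree
check_same_nodes <- function(w, partition = NULL, mask = NULL) {
  n <- nrow(w)
  if (!is.null(mask) && (nrow(mask) != n || ncol(mask) != n)) {
    abort("mask dimension does not match the connectivity matrix.")
  }
  if (!is.null(partition) && length(partition$membership) != n) {
    abort("partition length does not match the connectivity matrix.")
  }
  invisible(n)
}
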