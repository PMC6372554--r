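resolve_module <- function(partition, s) {
  if (is.character(s)) {
    if (is.null(partition$module_names)) abort("partition has no module names.")
    hit <- which(partition$module_names == s)
    if (length(hit) == 0) abort(sprintf("unknown module name '%s'.", s))
    if (length(hit) > 1) abort(sprintf("module name '%s' is ambiguous.", s))
    return(hit)
  }
  s <- as.integer(s)
  if (!s %in% partition$membership) abort(sprintf("unknown module id %d.", s))
  s
}

#' Intra-module connectivity
#'
#' Mean weight of the surviving (masked) edges with both endpoints in module
#' `s`: \eqn{C_s = \sum_{i,j \in s} k_{i,j} / l_s}, where \eqn{l_s} counts the
#' unordered edges actually present within the module. A module with no
#' surviving edges returns 0 with a warning.
#'
#' @param w Subject weighted connectivity matrix (typically Fisher-z).
#' @param mask Binary [fc_mask()] of surviving edges (`NULL`: all edges with
#'   nonzero weight).
#' @param partition Reference `fc_partition` (typically the healthy-control
#'   partition).
#' @param s Module id or module name.
#' @return Scalar \eqn{C_s}; attribute `l_edges` carries \eqn{l_s}.
#' @export
intra_module_connectivity <- function(w, mask = NULL, partition, s) {
  w <- unclass(w)
  if (is.null(mask)) mask <- (w != 0) * 1
  mask <- unclass(mask)
  check_same_nodes(w, partition, mask)
  sid <- resolve_module(partition, s)
  idx <- which(partition$membership == sid)
  if (!length(idx)) abort("module is empty.")
  sub_m <- mask[idx, idx, drop = FALSE]
  l_s <- sum(sub_m) / 2
  if (l_s == 0) {
    warn(sprintf("module %s has no surviving edges; C_s set to 0.", as.character(s)))
    return(structure(0, l_edges = 0))
  }
  c_s <- sum((w * mask)[idx, idx]) / 2 / l_s
  structure(c_s, l_edges = l_s)
}

#' Inter-module connectivity
#'
#' Mean weight of surviving edges with one endpoint in module `s` and the
#' other in module `t`: \eqn{C_{s,t} = \sum_{i \in s, j \in t} k_{i,j} /
#' l_{s,t}}. Symmetric in its module arguments; returns 0 with a warning when
#' no edges connect the two modules.
#'
#' @inheritParams intra_module_connectivity
#' @param s,t Distinct module ids or names.
#' @return Scalar \eqn{C_{s,t}}; attribute `l_edges` carries \eqn{l_{s,t}}.
#' @export
inter_module_connectivity <- function(w, mask = NULL, partition, s, t) {
  w <- unclass(w)
  if (is.null(mask)) mask <- (w != 0) * 1
  mask <- unclass(mask)
  check_same_nodes(w, partition, mask)
  sid <- resolve_module(partition, s)
  tid <- resolve_module(partition, t)
  if (sid == tid) abort("s and t must differ; use intra_module_connectivity().")
  idx_s <- which(partition$membership == sid)
  idx_t <- which(partition$membership == tid)
  l_st <- sum(mask[idx_s, idx_t, drop = FALSE])
  if (l_st == 0) {
    warn(sprintf("no surviving edges between modules %s and %s; C set to 0.",
                 as.character(s), as.character(t)))
    return(structure(0, l_edges = 0))
  }
  c_st <- sum((w * mask)[idx_s, idx_t]) / l_st
  structure(c_st, l_edges = l_st)
}

#' All module-level connectivity values for one subject
#'
#' Computes \eqn{C_s} for every module and \eqn{C_{s,t}} for every unordered
#' module pair of the reference partition, on the subject's masked weighted
#' matrix. With a 6-module partition this yields 6 intra and 15 inter values.
#'
#' @inheritParams intra_module_connectivity
#' @param subject_id,group Optional identifiers copied into the output.
#' @return Tibble: `subject_id`, `group`, `metric` (e.g. `intra_FP`,
#'   `inter_FP_Central`), `module_a`, `module_b`, `value`, `l_edges`.
#' @export
subject_module_metrics <- function(w, mask = NULL, partition,
                                   subject_id = NA_character_,
                                   group = NA_character_) {
  w <- unclass(w)
  if (is.null(mask)) mask <- (w != 0) * 1
  mask <- unclass(mask)
  check_same_nodes(w, partition, mask)
  mem <- partition$membership
  mods <- sort(unique(mem))
  nm <- partition$module_names %||% paste0("M", mods)
  # module-level aggregation gives every C_s and C_{s,t} in one pass;
  # equivalent to the per-pair operations (regression-tested against them)
  a_w <- module_aggregate(w * mask, mem)
  a_m <- module_aggregate(mask, mem)
  n_mod <- length(mods)
  pair_a <- integer(0); pair_b <- integer(0)
  for (a in seq_len(n_mod - 1)) {
    pair_a <- c(pair_a, rep(a, n_mod - a))
    pair_b <- c(pair_b, (a + 1):n_mod)
  }
  intra_l <- diag(a_m) / 2
  intra_v <- ifelse(intra_l > 0, (diag(a_w) / 2) / pmax(intra_l, 1), 0)
  inter_l <- a_m[cbind(pair_a, pair_b)]
  inter_v <- ifelse(inter_l > 0,
                    a_w[cbind(pair_a, pair_b)] / pmax(inter_l, 1), 0)
  tibble(
    subject_id = subject_id, group = group,
    metric = c(paste0("intra_", nm),
               paste0("inter_", nm[pair_a], "_", nm[pair_b])),
    module_a = c(nm, nm[pair_a]),
    module_b = c(nm, nm[pair_b]),
    value = unname(c(intra_v, inter_v)),
    l_edges = unname(c(intra_l, inter_l))
  )
}
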