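#' Regional correlation matrix with optional Fisher z transform
#'
#' Pearson correlation between all pairs of regional time series; the diagonal
#' is zeroed. With `fisher = TRUE` coefficients are variance-stabilized with
#' \eqn{z = \mathrm{arctanh}(r)}, clamping \eqn{|r|} at \eqn{1 - 10^{-15}} so
#' perfectly correlated pairs stay finite. Constant regions produce zero edges
#' with a warning.
#'
#' @param ts Numeric T x N matrix (timepoints x regions); column names become
#'   node labels.
#' @param fisher Apply the Fisher z transform (default `TRUE`).
#' @return An [fc_matrix()] of type `"z"` (or `"r"`).
#' @export
correlation_matrix <- function(ts, fisher = TRUE) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) abort("need at least 3 timepoints to correlate.")
  sds <- apply(ts, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(ts))
  if (any(const)) {
    warn(sprintf("%d constant region(s); their edges set to 0.", sum(const)))
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  if (fisher) {
    r <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    diag(r) <- 0
  }
  new_fc_matrix(r, type = if (fisher) "z" else "r")
}

#' Edge-wise FDR retention mask across subjects
#'
#' For each of the \eqn{N(N-1)/2} unordered edges, tests the subjects'
#' Fisher-z values against zero with a one-sample t-test (one-sided, greater,
#' by default: the aim is to remove weak or negative correlations), then
#' applies Benjamini-Hochberg across all edges at level `q`. The mask keeps
#' edges that are rejected and have positive group-mean z.
#'
#' Zero-variance edges are degenerate: they get p = 0 when the common value is
#' positive and p = 1 otherwise, and are reported via a message.
#'
#' @param z_mats List of subjects' Fisher-z matrices (identical dimension).
#' @param q FDR level (default 0.05).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An [fc_mask()] with provenance `"fdr"`; attribute `p_adjusted`
#'   carries the adjusted p-values on the upper triangle.
#' @export
edgewise_fdr_mask <- function(z_mats, q = 0.05, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(z_mats) < 3) abort("need at least 3 subjects for the edge-wise test.")
  n_nodes <- nrow(z_mats[[1]])
  ut <- upper.tri(z_mats[[1]])
  zmat <- vapply(z_mats, function(m) {
    if (nrow(m) != n_nodes) abort("subject matrices differ in dimension.")
    unclass(m)[ut]
  }, numeric(sum(ut)))              # edges x subjects
  n <- ncol(zmat)
  mu <- rowMeans(zmat)
  s <- apply(zmat, 1, sd)
  tstat <- mu / (s / sqrt(n))
  p <- switch(alternative,
    greater = pt(tstat, df = n - 1, lower.tail = FALSE),
    two.sided = 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  )
  degen <- s == 0
  if (any(degen)) {
    inform(sprintf("%d zero-variance edge(s); degenerate p assigned.", sum(degen)))
    p[degen] <- ifelse(mu[degen] > 0, 0, 1)
  }
  p_adj <- p.adjust(p, method = "BH")
  keep <- p_adj <= q & mu > 0
  mask <- matrix(0, n_nodes, n_nodes, dimnames = dimnames(z_mats[[1]]))
  mask[ut] <- as.numeric(keep)
  mask <- mask + t(mask)
  out <- new_fc_mask(mask, "fdr")
  attr(out, "p_adjusted") <- p_adj
  out
}

#' Masked group-average connectivity matrix
#'
#' Elementwise mean of the subjects' matrices with entries outside the mask
#' set to zero. The binary mask itself is carried along as attribute
#' `binary_mask` (the group-averaged binary connection matrix).
#'
#' @param mats List of subject matrices.
#' @param mask An [fc_mask()] (defaults to all ones off the diagonal).
#' @return An [fc_matrix()].
#' @export
group_average <- function(mats, mask = NULL) {
  n_nodes <- nrow(mats[[1]])
  if (is.null(mask)) {
    m <- matrix(1, n_nodes, n_nodes); diag(m) <- 0
    mask <- new_fc_mask(m, "manual")
  }
  check_same_nodes(mats[[1]], mask = mask)
  avg <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
  avg <- avg * unclass(mask)
  diag(avg) <- 0
  dimnames(avg) <- dimnames(mats[[1]])
  out <- new_fc_matrix(avg, type = attr(mats[[1]], "fc_type") %||% "z")
  attr(out, "binary_mask") <- mask
  out
}

#' Sparsity thresholding of a weighted network
#'
#' Keeps the \eqn{\lfloor s \cdot N(N-1)/2 \rfloor} largest-weight unordered
#' edges (sparsity = retained edges over all possible edges). Ties at the
#' cutoff break deterministically towards the lexicographically smaller
#' (i, j) node-index pair. Only positive-weight edges are eligible; if the
#' budget exceeds them, all positive edges are kept with a warning.
#'
#' @param w Weighted connectivity matrix.
#' @param sparsity Fraction in (0, 1].
#' @return An [fc_mask()] with provenance `"sparsity"`.
#' @export
sparsity_threshold <- function(w, sparsity) {
  if (!(sparsity > 0 && sparsity <= 1)) abort("`sparsity` must be in (0, 1].")
  w <- unclass(w)
  n <- nrow(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  budget <- floor(sparsity * n * (n - 1) / 2)
  pos <- wt > 0
  if (budget > sum(pos)) {
    warn(sprintf("budget %d exceeds %d positive-weight edges; keeping all positive.",
                 budget, sum(pos)))
    budget <- sum(pos)
  }
  keep_rows <- integer(0)
  if (budget > 0) {
    ord <- order(-wt, idx[, 1], idx[, 2])
    ord <- ord[pos[ord]]
    keep_rows <- ord[seq_len(budget)]
  }
  mask <- matrix(0, n, n, dimnames = dimnames(w))
  mask[idx[keep_rows, , drop = FALSE]] <- 1
  mask <- mask + t(mask)
  new_fc_mask(mask, "sparsity")
}

# connected-component labels of a logical/0-1 adjacency matrix (igraph-backed)
graph_components <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

#' Is the masked network one connected component?
#'
#' @param mask Binary adjacency / [fc_mask()].
#' @return `TRUE` iff a single component spans all nodes.
#' @export
is_connected <- function(mask) {
  max(graph_components(unclass(mask))) == 1L
}

#' Choose the sparsity threshold by whole-cohort connectedness
#'
#' Scans a sparsity grid and returns the smallest value at which every
#' subject's thresholded network is fully connected (every node reachable).
#' Because thresholded edge sets are nested in sparsity, per-subject
#' connectivity is monotone, so each subject is scanned ascending with early
#' stop.
#'
#' @param mats List of subject weighted matrices.
#' @param lo,hi,step Sparsity grid, default 0.05–0.30 by 0.01.
#' @return List with `selected` (scalar sparsity), `all_connected` (logical:
#'   did any grid value connect every subject), and `table`
#'   (tibble: sparsity, n_connected, selected).
#' @export
select_sparsity <- function(mats, lo = 0.05, hi = 0.30, step = 0.01) {
  if (!length(mats)) abort("no subject matrices supplied.")
  grid <- seq(lo, hi, by = step)
  first_ok <- vapply(mats, function(w) {
    for (g in seq_along(grid)) {
      if (is_connected(sparsity_threshold(w, grid[g]))) return(g)
    }
    length(grid) + 1L
  }, integer(1))
  n_connected <- vapply(seq_along(grid),
                        function(g) sum(first_ok <= g), integer(1))
  all_ok <- n_connected == length(mats)
  if (any(all_ok)) {
    sel_idx <- which(all_ok)[1]
    all_connected <- TRUE
  } else {
    sel_idx <- which.max(n_connected)
    all_connected <- FALSE
    warn("no sparsity in range connects every subject; returning max-coverage value.")
  }
  list(
    selected = grid[sel_idx],
    all_connected = all_connected,
    table = tibble(sparsity = grid, n_connected = n_connected,
                   selected = seq_along(grid) == sel_idx)
  )
}
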