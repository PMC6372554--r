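#' Planted block correlation matrix
#'
#' Builds the N x N correlation matrix of the planted modular structure:
#' entry (i, j) is `r_intra[m]` when both nodes sit in module m, `r_inter`
#' otherwise, plus any additive deltas for specific module pairs. If the raw
#' matrix is not positive semidefinite (large deltas can break it), the
#' nearest-PSD repair is applied: eigenvalues are clipped at 1e-8 and the
#' diagonal renormalized to 1. A repair is reported (message) and recorded in
#' the attributes `repaired` and `frobenius_repair` (the Frobenius distance
#' between raw and repaired matrices).
#'
#' @param partition An `fc_partition` (module names used to resolve deltas) or
#'   an integer membership vector.
#' @param r_intra Within-module correlation, scalar or one per module.
#' @param r_inter Between-module correlation.
#' @param effect_deltas Optional tibble (`module_a`, `module_b`, `delta`);
#'   `module_a == module_b` shifts the intra-module block (off-diagonal only).
#' @return Symmetric unit-diagonal PSD matrix with node labels.
#' @export
planted_covariance <- function(partition, r_intra, r_inter,
                               effect_deltas = NULL) {
  if (!inherits(partition, "fc_partition")) {
    partition <- new_fc_partition(as.integer(partition))
  }
  m <- partition$membership
  n <- length(m)
  n_mod <- max(m)
  if (length(r_intra) == 1) r_intra <- rep(r_intra, n_mod)
  if (length(r_intra) != n_mod) abort("r_intra length must match module count.")
  sigma <- matrix(r_inter, n, n)
  for (s in seq_len(n_mod)) {
    idx <- m == s
    sigma[idx, idx] <- r_intra[s]
  }
  if (!is.null(effect_deltas) && nrow(effect_deltas) > 0) {
    for (k in seq_len(nrow(effect_deltas))) {
      a <- resolve_module(partition, effect_deltas$module_a[k])
      b <- resolve_module(partition, effect_deltas$module_b[k])
      ia <- m == a; ib <- m == b
      sigma[ia, ib] <- sigma[ia, ib] + effect_deltas$delta[k]
      if (a != b) sigma[ib, ia] <- sigma[ib, ia] + effect_deltas$delta[k]
    }
  }
  diag(sigma) <- 1
  off <- sigma[upper.tri(sigma)]
  if (any(abs(off) >= 1)) {
    abort("effect deltas push a correlation to |r| >= 1.")
  }
  labels <- names(m) %||% paste0("R", seq_len(n))
  dimnames(sigma) <- list(labels, labels)
  ev <- eigen(sigma, symmetric = TRUE)
  repaired <- FALSE
  fro <- 0
  if (min(ev$values) < 1e-8) {
    vals <- pmax(ev$values, 1e-8)
    fixed <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(fixed))
    fixed <- fixed / tcrossprod(d)
    fixed <- (fixed + t(fixed)) / 2
    diag(fixed) <- 1
    fro <- sqrt(sum((fixed - sigma)^2))
    inform(sprintf(
      "planted covariance repaired to PSD (Frobenius distance %.4g).", fro))
    dimnames(fixed) <- dimnames(sigma)
    sigma <- fixed
    repaired <- TRUE
  }
  structure(sigma, repaired = repaired, frobenius_repair = fro)
}

# T x N draw from N(0, sigma) plus optional white observation noise.
rmvn_ts <- function(n_t, sigma, noise_sd = 0) {
  n <- nrow(sigma)
  cf <- tryCatch(chol(sigma),
                 error = function(e) chol(sigma + diag(1e-8, n)))
  z <- matrix(rnorm(n_t * n), n_t, n)
  x <- z %*% cf
  if (noise_sd > 0) x <- x + matrix(rnorm(n_t * n, sd = noise_sd), n_t, n)
  colnames(x) <- colnames(sigma)
  x
}
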