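# Independent oracles used across the suite. These deliberately use naive
# direct computation (double loops, exhaustive enumeration) so they share no
# code path with the package implementation.

# Eq.-style weighted modularity by brute-force double loop over ordered pairs.
oracle_modularity <- function(w, m) {
  l <- sum(w)
  k <- rowSums(w)
  tot <- 0
  n <- nrow(w)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (m[i] == m[j]) tot <- tot + w[i, j] - k[i] * k[j] / l
    }
  }
  tot / l
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxid + 1)) {
      recurse(c(prefix, v), max(maxid, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive maximum modularity by enumerating every partition (n <= 8).
oracle_best_partition <- function(w) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(m) oracle_modularity(w, m), numeric(1))
  best <- which.max(qs)
  list(q = qs[best], membership = parts[[best]])
}

# Union-find connectivity oracle.
oracle_connected <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j] > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1
}

# Direct summation oracles for intra/inter-module connectivity.
oracle_intra <- function(w, mask, membership, s) {
  idx <- which(membership == s)
  tot <- 0; cnt <- 0
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      if (mask[i, j] > 0) {
        tot <- tot + w[i, j]
        cnt <- cnt + 1
      }
    }
  }
  if (cnt == 0) 0 else tot / cnt
}

oracle_inter <- function(w, mask, membership, s, t) {
  is_ <- which(membership == s); it <- which(membership == t)
  tot <- 0; cnt <- 0
  for (i in is_) {
    for (j in it) {
      if (mask[i, j] > 0) {
        tot <- tot + w[i, j]
        cnt <- cnt + 1
      }
    }
  }
  if (cnt == 0) 0 else tot / cnt
}

# Random symmetric non-negative weighted graph.
rand_wgraph <- function(n, density = 0.6) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[runif(length(ut)) < density]
  w[on] <- runif(length(on), 0.1, 1)
  w <- w + t(w)
  diag(w) <- 0
  w
}

# Monte-Carlo framewise-displacement oracle: RMS displacement of points
# uniform in an 80 mm ball under the relative rigid transform between two
# parameter rows (rotations in degrees, Rx Ry Rz order, same convention as
# the motion file format).
oracle_fd_mc <- function(par_prev, par_cur, radius = 80, n_pts = 10000) {
  rot <- function(deg) {
    th <- deg * pi / 180
    rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
    ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                   -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
    rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                   0, 0, 1), 3, byrow = TRUE)
    rx %*% ry %*% rz
  }
  u <- matrix(rnorm(3 * n_pts), n_pts, 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- u * radius * runif(n_pts)^(1 / 3)   # uniform in the solid ball
  m1 <- rot(par_prev[4:6]); b1 <- par_prev[1:3]
  m2 <- rot(par_cur[4:6]);  b2 <- par_cur[1:3]
  # head-space point x = m1^{-1}(y - b1); displacement = (m2 x + b2) - y
  x <- sweep(pts, 2, b1) %*% m1              # = t(m1^T (y-b1)) rowwise
  moved <- x %*% t(m2)
  moved <- sweep(moved, 2, b2, `+`)
  sqrt(mean(rowSums((moved - pts)^2)))
}

# Small, fast synthetic configuration for unit tests.
tiny_config <- function(seed = 11, ...) {
  fc_sim_config(
    n_patients = 3, n_controls = 3, n_timepoints = 60,
    module_sizes = c(A = 5, B = 5),
    effect_map = NULL, motion_outliers = 1, crlb_outliers = 1,
    seed = seed, ...
  )
}

# The default-condition cohort/analysis, computed once and cached for all
# test files that need the full-scale run.
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(fc_sim_config(seed = 42))
      an <- suppressWarnings(run_full_analysis(co))
      cache <<- list(cohort = co, analysis = an)
    }
    cache
  }
})
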