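test_that("correlation matrix matches a textbook computation and clamps r = 1", {
  # fixed 3-column toy table, oracle = explicit covariance / sd formula
  ts <- cbind(a = c(1, 2, 4, 3, 5), b = c(2, 1, 3, 5, 4), c = c(5, 3, 1, 2, 4))
  cm <- correlation_matrix(ts, fisher = FALSE)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      if (i == j) next
      x <- ts[, i]; y <- ts[, j]
      oracle[i, j] <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    }
  }
  expect_equal(unname(unclass(cm)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  # Fisher z: finite for identical columns, tanh recovers r off-diagonal
  ts2 <- cbind(ts, d = ts[, 1])
  zm <- correlation_matrix(ts2, fisher = TRUE)
  expect_true(all(is.finite(zm)))
  expect_gt(zm[1, 4], 17)            # clamped arctanh(1 - 1e-15)
  expect_equal(tanh(zm[1, 2]), cm[1, 2], tolerance = 1e-12)

  # independent noise at large T: negligible correlation
  set.seed(77)
  big <- matrix(rnorm(10000 * 3), 10000, 3)
  rm_ <- correlation_matrix(big, fisher = FALSE)
  expect_lt(max(abs(unclass(rm_))), 0.05)

  expect_error(correlation_matrix(big[1:2, ]), "3 timepoints")
  const <- cbind(rnorm(30), rep(1, 30))
  expect_warning(cc <- correlation_matrix(const), "constant")
  expect_equal(unname(unclass(cc)[, 2]), c(0, 0))
})

test_that("edge-wise FDR mask keeps planted edges and drops nulls", {
  n_nodes <- 10
  n_subj <- 26
  # all-zero matrices: nothing retained (degenerate zero-variance edges)
  zeros <- replicate(n_subj, matrix(0, n_nodes, n_nodes), simplify = FALSE)
  m0 <- suppressMessages(edgewise_fdr_mask(zeros))
  expect_equal(sum(m0), 0)

  # one strong planted edge among nulls: exactly that edge in >= 95/100 seeds
  hits <- 0
  extras <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    mats <- lapply(seq_len(n_subj), function(k) {
      w <- matrix(0, n_nodes, n_nodes)
      e <- matrix(rnorm(n_nodes^2, sd = 0.1), n_nodes, n_nodes)
      e <- (e + t(e)) / 2
      w <- w + e
      w[1, 2] <- w[2, 1] <- w[1, 2] + 0.4
      diag(w) <- 0
      w
    })
    msk <- edgewise_fdr_mask(mats, q = 0.05)
    if (msk[1, 2] == 1) hits <- hits + 1
    extras <- extras + (sum(msk) / 2 - msk[1, 2])
  }
  expect_gte(hits, 95)
  expect_lt(extras / 100, 1)         # near-clean elsewhere on average

  # the Benjamini-Hochberg step: the adjusted-p convention the mask relies on
  p <- c(0.001, 0.02, 0.04, 0.9)
  expect_equal(sum(p.adjust(p, "BH") <= 0.05), 2)
})

test_that("group average respects the mask", {
  set.seed(12)
  a <- matrix(rnorm(25), 5, 5); a <- (a + t(a)) / 2; diag(a) <- 0
  b <- matrix(rnorm(25), 5, 5); b <- (b + t(b)) / 2; diag(b) <- 0
  full <- matrix(1, 5, 5); diag(full) <- 0
  avg <- group_average(list(a, b), fc_mask(full))
  expect_equal(unclass(avg), (a + b) / 2 * full, ignore_attr = TRUE)
  empty <- fc_mask(matrix(0, 5, 5))
  expect_equal(sum(abs(group_average(list(a, b), empty))), 0)
  # random mask: direct recomputation
  msk <- matrix(0, 5, 5); msk[1, 3] <- msk[3, 1] <- 1; msk[2, 5] <- msk[5, 2] <- 1
  avg2 <- group_average(list(a, b), fc_mask(msk))
  expect_equal(unclass(avg2), (a + b) / 2 * msk, ignore_attr = TRUE)
})

test_that("sparsity thresholding: edge budget, ties, monotone nesting", {
  n <- 90
  set.seed(3)
  w <- matrix(runif(n * n, 0.01, 1), n, n); w <- (w + t(w)) / 2; diag(w) <- 0
  m15 <- sparsity_threshold(w, 0.15)
  expect_equal(sum(m15) / 2, 600)          # floor(0.15 * 4005)
  m1 <- sparsity_threshold(w, 1)
  expect_equal(sum(m1) / 2, n * (n - 1) / 2)

  # deterministic lexicographic tie-break at the cutoff
  wt <- matrix(0, 4, 4)
  wt[1, 4] <- wt[4, 1] <- 0.5
  wt[2, 3] <- wt[3, 2] <- 0.5
  mt <- sparsity_threshold(wt, 1 / 6)      # budget 1 of 6 possible edges
  expect_equal(mt[1, 4], 1)                # (1,4) < (2,3) lexicographically
  expect_equal(sum(mt) / 2, 1)

  # budget beyond available positive edges: keep all positive, warn
  wp <- matrix(0, 4, 4); wp[1, 2] <- wp[2, 1] <- 0.3
  expect_warning(mp <- sparsity_threshold(wp, 1), "positive")
  expect_equal(sum(mp) / 2, 1)

  # nesting: mask(s1) subset of mask(s2) for s1 <= s2
  s_grid <- c(0.05, 0.1, 0.2, 0.3)
  masks <- lapply(s_grid, function(s) unclass(sparsity_threshold(w, s)))
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i]] <= masks[[i + 1]]))
  }
})

test_that("connectivity agrees with a union-find oracle", {
  path <- matrix(0, 5, 5)
  for (i in 1:4) path[i, i + 1] <- path[i + 1, i] <- 1
  expect_true(is_connected(path))
  iso <- path; iso[4, 5] <- iso[5, 4] <- 0
  expect_false(is_connected(iso))
  set.seed(19)
  for (k in 1:20) {
    adj <- (rand_wgraph(8, density = runif(1, 0.1, 0.5)) > 0) * 1
    expect_equal(is_connected(adj), oracle_connected(adj))
  }
})

test_that("sparsity selection returns the smallest connecting grid value", {
  set.seed(4)
  mats <- replicate(3, {
    w <- matrix(runif(100, 0.2, 1), 10, 10); w <- (w + t(w)) / 2; diag(w) <- 0
    w
  }, simplify = FALSE)
  sel <- select_sparsity(mats, lo = 0.05, hi = 0.3, step = 0.05)
  # dense positive matrices connect at the lowest sparsity... if 5% of 45
  # edges (=2 edges) cannot span 10 nodes, the smallest feasible value wins
  expect_true(sel$selected >= 0.05 && sel$selected <= 0.3)
  expect_true(sel$table$selected[which(sel$table$sparsity == sel$selected)])
  # every grid value reported with its connected-subject count
  expect_equal(nrow(sel$table), 6)
  expect_true(all(sel$table$n_connected >= 0 & sel$table$n_connected <= 3))
  # connectivity is monotone in sparsity
  expect_true(all(diff(sel$table$n_connected) >= 0))

  # soft failure: no sparsity connects a graph with an isolated-by-weight node
  w <- matrix(0, 6, 6)
  w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1; w[5, 6] <- w[6, 5] <- 1
  msgs <- testthat::capture_warnings(
    sel2 <- select_sparsity(list(w), lo = 0.05, hi = 0.3))
  expect_true(any(grepl("max-coverage", msgs)))
  expect_false(sel2$all_connected)
})

test_that("matrices round-trip through the labeled TSV format", {
  set.seed(6)
  w <- rand_wgraph(8)
  dimnames(w) <- list(paste0("r", 1:8), paste0("r", 1:8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(w, path)
  back <- read_matrix_tsv(path)
  expect_equal(back, w, tolerance = 1e-12)
})

test_that("the default cohort's selected sparsity is deterministic and in range", {
  an <- default_run()$analysis
  expect_true(an$selected_sparsity >= 0.05 && an$selected_sparsity <= 0.30)
  expect_true(an$sparsity_all_connected)
})
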