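test_that("planted covariance realizes the block structure", {
  part <- planted_partition(c(A = 2, B = 2))
  sig <- planted_covariance(part, r_intra = 0.5, r_inter = 0)
  expected <- matrix(0, 4, 4)
  expected[1:2, 1:2] <- 0.5
  expected[3:4, 3:4] <- 0.5
  diag(expected) <- 1
  expect_equal(unname(unclass(sig)), expected, ignore_attr = TRUE)
  # degenerate case: no correlation anywhere -> identity
  sig0 <- planted_covariance(part, r_intra = 0, r_inter = 0)
  expect_equal(unname(unclass(sig0)), diag(4), ignore_attr = TRUE)
})

test_that("per-module r_intra and intra-block deltas are honored", {
  part <- planted_partition(c(A = 3, B = 2))
  sig <- planted_covariance(part, r_intra = c(0.6, 0.3), r_inter = 0.1,
                            effect_deltas = tibble::tibble(
                              module_a = "A", module_b = "A", delta = 0.2))
  expect_equal(sig[1, 2], 0.8)     # 0.6 + 0.2, off-diagonal only
  expect_equal(sig[1, 1], 1)
  expect_equal(sig[4, 5], 0.3)
  expect_equal(sig[1, 4], 0.1)
})

test_that("default 90-node patient covariance is PSD (eigendecomposition oracle)", {
  part <- planted_partition()
  sig <- suppressMessages(
    planted_covariance(part, 0.5, 0.1, default_effect_map())
  )
  ev <- eigen(unclass(sig), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(unname(diag(sig)), rep(1, 90))
  expect_true(isSymmetric(matrix(as.numeric(sig), 90, 90)))
  # the default deltas keep the matrix PSD outright: no repair needed
  expect_false(attr(sig, "repaired"))
  expect_equal(attr(sig, "frobenius_repair"), 0)
})

test_that("an infeasible correlation pattern is repaired to PSD and reported", {
  # triangle violation across modules: A~B = A~C = 0.9 but B~C = -0.9
  part <- planted_partition(c(A = 2, B = 2, C = 2))
  deltas <- tibble::tibble(module_a = c("A", "A", "B"),
                           module_b = c("B", "C", "C"),
                           delta = c(0.9, 0.9, -0.9))
  expect_message(
    sig <- planted_covariance(part, 0.5, 0, deltas),
    "repaired"
  )
  expect_true(attr(sig, "repaired"))
  expect_gt(attr(sig, "frobenius_repair"), 0)
  ev <- eigen(unclass(sig), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(unname(diag(sig)), rep(1, 6))
})

test_that("deltas pushing |r| to 1 are rejected", {
  part <- planted_partition(c(A = 2, B = 2))
  expect_error(
    planted_covariance(part, 0.9, 0.1,
                       tibble::tibble(module_a = "A", module_b = "A",
                                      delta = 0.2)),
    "delta"
  )
})

test_that("same seed gives bit-identical cohorts, different seeds differ", {
  c1 <- suppressMessages(generate_cohort(tiny_config(seed = 42)))
  c2 <- suppressMessages(generate_cohort(tiny_config(seed = 42)))
  expect_identical(c1$subjects$ts, c2$subjects$ts)
  expect_identical(c1$subjects$motion, c2$subjects$motion)
  expect_identical(c1$metabolites, c2$metabolites)
  expect_identical(c1$clinical, c2$clinical)
  c3 <- suppressMessages(generate_cohort(tiny_config(seed = 43)))
  expect_false(identical(c1$subjects$ts, c3$subjects$ts))
  # planted structure (labels, partition) is seed-independent
  expect_identical(c1$region_labels, c3$region_labels)
  expect_identical(c1$partition$membership, c3$partition$membership)
})

test_that("sample correlations converge to the planted values (LLN)", {
  cfg <- fc_sim_config(
    n_patients = 1, n_controls = 1, n_timepoints = 10000,
    module_sizes = c(A = 4, B = 4), r_intra = 0.5, r_inter = 0.1,
    effect_map = NULL, fc_between_sd = 0, obs_noise_sd = 0,
    motion_outliers = 0, crlb_outliers = 0, seed = 5
  )
  co <- generate_cohort(cfg)
  r <- cor(co$subjects$ts[[1]])
  within_a <- r[1:4, 1:4][upper.tri(diag(4))]
  within_b <- r[5:8, 5:8][upper.tri(diag(4))]
  between <- r[1:4, 5:8]
  expect_true(all(abs(within_a - 0.5) < 0.02))
  expect_true(all(abs(within_b - 0.5) < 0.02))
  expect_true(all(abs(between - 0.1) < 0.02))
})

test_that("metabolite coupling is linear in the planted coupling for controls only", {
  cfg <- fc_sim_config(coupling_noise_sd = 0, seed = 9)
  co <- generate_cohort(cfg)
  met <- co$metabolites[co$metabolites$metabolite == "NAA", ]
  df <- merge(met, co$subjects[, c("subject_id", "group", "planted_fpc")])
  ctrl <- df[df$group == "control", ]
  pat <- df[df$group == "patient", ]
  # zero observation noise: control concentrations are an exact line
  fit <- lm(concentration ~ planted_fpc, data = ctrl)
  expect_equal(unname(coef(fit)[2]), cfg$coupling_slope, tolerance = 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  # patients are decoupled: slope 0, so concentration is constant
  expect_lt(diff(range(pat$concentration)), 1e-8)
})

test_that("patient symptom scores are monotone in the planted couplings", {
  co <- generate_cohort(fc_sim_config(seed = 3, clinical_coupling = 0.65))
  pat <- co$subjects[co$subjects$group == "patient", ]
  df <- merge(co$clinical, pat[, c("subject_id", "planted_fpc", "planted_fph")])
  expect_lt(cor(df$panss_gen, df$planted_fpc, method = "spearman"), 0)
  expect_gt(cor(df$panss_gen, df$planted_fph, method = "spearman"), 0)
  expect_lt(cor(df$panss_total, df$planted_fpc, method = "spearman"), 0)
})

test_that("recruited pool carries the planted-to-fail subjects", {
  co <- default_run()$cohort
  tb <- table(co$subjects$group)
  expect_equal(unname(tb[["patient"]]), 24)   # 20 + 3 motion + 1 crlb
  expect_equal(unname(tb[["control"]]), 29)   # 26 + 3 motion
  expect_equal(sum(co$subjects$planted_outlier != "none"), 7)
  crlb_subj <- co$subjects$subject_id[co$subjects$planted_outlier == "crlb"]
  bad <- co$metabolites[co$metabolites$subject_id %in% crlb_subj, ]
  expect_true(all(bad$crlb_percent >= 20))
})

test_that("cohort round-trips through the on-disk plain-text layout", {
  co <- suppressMessages(generate_cohort(tiny_config(seed = 2)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(back$subjects$subject_id, co$subjects$subject_id)
  expect_equal(back$subjects$group, co$subjects$group)
  for (i in seq_len(nrow(co$subjects))) {
    expect_equal(unname(back$subjects$ts[[i]]), unname(co$subjects$ts[[i]]),
                 tolerance = 1e-9)
    expect_equal(unname(back$subjects$motion[[i]]),
                 unname(co$subjects$motion[[i]]), tolerance = 1e-9)
  }
  expect_equal(back$partition$membership, co$partition$membership)
  expect_equal(back$clinical$panss_total, co$clinical$panss_total)
  expect_equal(back$config$seed, co$config$seed)
})

test_that("configuration invariants are enforced", {
  expect_error(fc_sim_config(module_sizes = c(A = 5, B = 5), r_intra = 0.1,
                             r_inter = 0.3, effect_map = NULL),
               "r_inter")
  expect_error(fc_sim_config(n_patients = 0), "positive")
  expect_error(fc_sim_config(module_sizes = c(5, 5)), "named")
})
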