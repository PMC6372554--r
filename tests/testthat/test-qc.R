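test_that("framewise displacement matches closed-form and Monte-Carlo oracles", {
  # constant motion -> FD identically zero
  m <- matrix(rep(c(0.3, -0.2, 0.1, 0.5, -0.4, 0.2), each = 10), 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))

  # pure 3 mm translation step: rotation term vanishes, FD = 3
  m <- matrix(0, 5, 6)
  m[3:5, 1] <- 3
  fd <- framewise_displacement(m)
  expect_equal(fd, c(0, 0, 3, 0, 0))

  # single-axis rotation step of 1 degree vs ball-average oracle
  prev <- rep(0, 6)
  cur <- c(0, 0, 0, 1, 0, 0)
  m <- rbind(prev, cur)
  fd <- framewise_displacement(m)[2]
  set.seed(401)
  mc <- oracle_fd_mc(prev, cur)
  expect_equal(fd, mc, tolerance = 0.02)

  # combined rotation + translation, random parameters
  set.seed(402)
  for (k in 1:5) {
    prev <- c(rnorm(3, 0, 0.5), rnorm(3, 0, 0.5))
    cur <- prev + c(rnorm(3, 0, 0.3), rnorm(3, 0, 0.3))
    fd <- framewise_displacement(rbind(prev, cur))[2]
    mc <- oracle_fd_mc(prev, cur)
    expect_equal(fd, mc, tolerance = 0.02)
  }

  expect_error(framewise_displacement(matrix(c(NA, rep(0, 11)), 2, 6)),
               "finite")
})

test_that("friston24 layout: params, backshift, squares", {
  expect_equal(friston24(matrix(0, 8, 6)), matrix(0, 8, 24),
               ignore_attr = TRUE)
  set.seed(7)
  m <- matrix(rnorm(60), 10, 6)
  f <- friston24(m)
  expect_equal(dim(f), c(10, 24))
  expect_equal(unname(f[, 1:6]), m)
  expect_equal(unname(f[, 7:12]), rbind(0, m[-10, ]))   # one-lag backshift
  expect_equal(unname(f[, 13:18]), m^2)
  expect_equal(unname(f[, 19:24]), rbind(0, m[-10, ])^2)
})

test_that("motion exclusion applies gross rules then the group FD rule", {
  zeros <- matrix(0, 20, 6)
  tbl <- tibble::tibble(
    subject_id = paste0("s", 1:4), group = "control",
    motion = list(zeros, zeros, zeros, zeros)
  )
  rep0 <- motion_exclusion(tbl)
  expect_true(all(rep0$included))

  # the FD-rule statistics must exclude gross-motion failures: a huge-motion
  # subject would otherwise inflate the group SD and hide an FD outlier
  set.seed(31)
  mk <- function(scale, spike = 0) {
    m <- matrix(rnorm(120, sd = 0.02 * scale), 20, 6)
    m[, 1] <- m[, 1] + spike
    m
  }
  traces <- c(lapply(1:10, function(i) mk(1)),
              list(mk(20), mk(1, spike = 5)))
  tbl <- tibble::tibble(
    subject_id = paste0("s", 1:12), group = "patient", motion = traces
  )
  rep1 <- motion_exclusion(tbl)
  expect_equal(rep1$reason[12], "translation")
  expect_false(rep1$included[11])         # mean-FD outlier caught
  expect_equal(rep1$reason[11], "mean_fd")
  expect_true(all(rep1$included[1:10]))
  # fd limit computed over the subjects passing the gross rules only
  passing_fd <- rep1$mean_fd[1:11]
  expect_equal(rep1$fd_limit[1],
               mean(passing_fd) + 2 * sd(passing_fd))
})

test_that("default synthetic cohort: exactly the planted outliers are excluded", {
  co <- default_run()$cohort
  qc <- qc_cohort(co)
  excluded <- qc$subject_id[!qc$included]
  planted <- co$subjects$subject_id[co$subjects$planted_outlier != "none"]
  expect_setequal(excluded, planted)
  expect_equal(sum(qc$included & qc$group == "patient"), 20)
  expect_equal(sum(qc$included & qc$group == "control"), 26)
  # every exclusion carries a reason
  expect_true(all(!is.na(qc$reason[!qc$included])))
})

test_that("nuisance regression matches a pseudoinverse oracle and is idempotent", {
  set.seed(21)
  ts <- matrix(rnorm(50 * 4), 50, 4)
  x <- matrix(rnorm(50 * 5), 50, 5)

  # no regressors: column demeaning
  expect_equal(nuisance_regress(ts), scale(ts, scale = FALSE),
               ignore_attr = TRUE)

  res <- nuisance_regress(ts, x)
  design <- cbind(1, x)
  oracle <- ts - design %*% (solve(t(design) %*% design) %*% t(design) %*% ts)
  expect_equal(res, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(t(res) %*% design)) / max(abs(ts)), 1e-8)
  # idempotent
  expect_equal(nuisance_regress(res, x), res, tolerance = 1e-10)

  # a region equal to a regressor is fitted perfectly
  ts2 <- cbind(x[, 1], ts)
  res2 <- nuisance_regress(ts2, x)
  expect_lt(max(abs(res2[, 1])), 1e-10)

  # rank deficiency names the offending column
  xdup <- cbind(a = x[, 1], b = x[, 1])
  expect_error(nuisance_regress(ts, xdup), "b")
})

test_that("detrend/band-pass keeps in-band signal and kills trend and out-of-band", {
  tt <- 256; tr <- 2
  tvec <- seq_len(tt)
  # linear ramp is removed entirely
  ramp <- matrix(5 + 0.3 * tvec, tt, 1)
  expect_lt(max(abs(detrend_bandpass(ramp, tr))), 1e-10)

  amp_of <- function(x, f) {
    s <- sin(2 * pi * f * tr * tvec); c_ <- cos(2 * pi * f * tr * tvec)
    fit <- lm(x ~ s + c_)
    sqrt(sum(coef(fit)[2:3]^2))
  }
  x_in <- matrix(sin(2 * pi * 0.05 * tr * tvec), tt, 1)
  y_in <- detrend_bandpass(x_in, tr)
  expect_equal(amp_of(y_in[, 1], 0.05), 1, tolerance = 0.01)

  x_out <- matrix(sin(2 * pi * 0.2 * tr * tvec), tt, 1)
  y_out <- detrend_bandpass(x_out, tr)
  expect_lt(amp_of(y_out[, 1], 0.2), 0.01)

  # linearity: filter(a x + b y) = a filter(x) + b filter(y)
  set.seed(8)
  u <- matrix(rnorm(tt), tt, 1); v <- matrix(rnorm(tt), tt, 1)
  lhs <- detrend_bandpass(2 * u - 3 * v, tr)
  rhs <- 2 * detrend_bandpass(u, tr) - 3 * detrend_bandpass(v, tr)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # zero mean output
  expect_lt(abs(mean(detrend_bandpass(u, tr))), 1e-10)

  expect_error(detrend_bandpass(u, tr, low_hz = 0.05, high_hz = 0.3),
               "Nyquist")
})

test_that("CRLB filter uses a strict < threshold, per record", {
  rec <- tibble::tibble(
    subject_id = c("a", "a", "b", "b", "c"),
    metabolite = c("NAA", "Glx", "NAA", "GABA+", "NAA"),
    crlb_percent = c(19.9, 20.0, 5, 35, 20.0001)
  )
  kept <- suppressMessages(crlb_filter(rec))
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$crlb_percent < 20))
  expect_equal(nrow(attr(kept, "excluded")), 3)
  # empty input passes through
  empty <- crlb_filter(rec[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("CSF partial-volume correction", {
  rec <- tibble::tibble(concentration = c(8, 12), f_csf = c(0.2, 0))
  out <- csf_correct(rec)
  expect_equal(out$concentration_corrected, c(10, 12))
  set.seed(10)
  rec2 <- tibble::tibble(concentration = runif(20, 1, 15),
                         f_csf = runif(20, 0, 0.5))
  out2 <- csf_correct(rec2)
  expect_equal(out2$concentration_corrected,
               rec2$concentration / (1 - rec2$f_csf))
  expect_error(csf_correct(tibble::tibble(concentration = 1, f_csf = 1)),
               "f_csf")
})
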