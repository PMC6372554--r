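new_fc_stat <- function(method, estimate, statistic, df, p, n,
                        flags = character(0)) {
  structure(
    list(method = method, estimate = estimate, statistic = statistic,
         df = df, p.value = p, n = n, flags = flags),
    class = "fc_stat"
  )
}

#' @export
print.fc_stat <- function(x, ...) {
  cat(sprintf("<fc_stat> %s\n  estimate = %.4g, statistic = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$estimate, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
tidy.fc_stat <- function(x, ...) {
  tibble(method = x$method, estimate = x$estimate, statistic = x$statistic,
         df = x$df, p.value = x$p.value, n = paste(x$n, collapse = ","),
         flags = paste(x$flags, collapse = ","))
}

#' Two-tailed independent two-sample t-test
#'
#' Welch's unequal-variance statistic by default,
#' \eqn{t = (\bar a - \bar b)/\sqrt{s_a^2/n_a + s_b^2/n_b}} with
#' Welch-Satterthwaite degrees of freedom; `welch = FALSE` gives the pooled
#' form. Accepts either raw samples or printed summary statistics, so group
#' contrasts reported as mean +/- SD can be re-evaluated directly.
#'
#' @param a,b Numeric vectors (ignored when `summary` is given).
#' @param welch Use the Welch statistic (default `TRUE`).
#' @param summary Optional list/row with `mean_a, sd_a, n_a, mean_b, sd_b,
#'   n_b`.
#' @return An `fc_stat` (see [tidy()]).
#' @export
two_sample_ttest <- function(a = NULL, b = NULL, welch = TRUE, summary = NULL) {
  if (is.null(summary)) {
    if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2.")
    summary <- list(mean_a = mean(a), sd_a = sd(a), n_a = length(a),
                    mean_b = mean(b), sd_b = sd(b), n_b = length(b))
  }
  s <- summary
  va <- s$sd_a^2 / s$n_a
  vb <- s$sd_b^2 / s$n_b
  if (va + vb == 0) abort("zero combined variance: t-test undefined.")
  est <- s$mean_a - s$mean_b
  if (welch) {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (s$n_a - 1) + vb^2 / (s$n_b - 1))
  } else {
    sp2 <- ((s$n_a - 1) * s$sd_a^2 + (s$n_b - 1) * s$sd_b^2) /
      (s$n_a + s$n_b - 2)
    se <- sqrt(sp2 * (1 / s$n_a + 1 / s$n_b))
    df <- s$n_a + s$n_b - 2
  }
  tstat <- est / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  new_fc_stat(if (welch) "welch_ttest" else "pooled_ttest",
              est, tstat, df, p, n = c(s$n_a, s$n_b),
              flags = if (welch) "welch" else character(0))
}

#' Pearson correlation with t-based two-tailed p
#'
#' \eqn{r} with \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of
#' freedom. Accepts raw vectors or a printed `(r, n)` summary.
#'
#' @param x,y Numeric vectors.
#' @param r,n Summary-statistic input (used when `x` is missing/NULL).
#' @return An `fc_stat`.
#' @export
pearson_corr <- function(x = NULL, y = NULL, r = NULL, n = NULL) {
  if (is.null(r)) {
    if (length(x) < 3) abort("need n >= 3.")
    if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined.")
    r <- cor(x, y)
    n <- length(x)
  }
  df <- n - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  new_fc_stat("pearson", r, tstat, df, p, n = n)
}

#' Spearman rank correlation with t-approximation p
#'
#' \eqn{\rho} is the Pearson correlation of mid-ranks (average ranks for
#' ties); the two-tailed p uses the same t-approximation on \eqn{n-2} degrees
#' of freedom as [pearson_corr()], matching standard statistical-package
#' output at moderate n. Accepts raw vectors or a printed `(rho, n)` summary.
#'
#' @param x,y Numeric vectors.
#' @param rho,n Summary-statistic input.
#' @return An `fc_stat`.
#' @export
spearman_corr <- function(x = NULL, y = NULL, rho = NULL, n = NULL) {
  if (is.null(rho)) {
    if (length(x) < 4) abort("need n >= 4.")
    rx <- rank(x); ry <- rank(y)
    if (sd(rx) == 0 || sd(ry) == 0) abort("constant ranks: rho undefined.")
    rho <- cor(rx, ry)
    n <- length(x)
  }
  df <- n - 2
  tstat <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  new_fc_stat("spearman", rho, tstat, df, p, n = n)
}

grubbs_critical <- function(n, alpha = 0.05) {
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Iterative Grubbs outlier screening
#'
#' Repeatedly applies the two-sided Grubbs test at level `alpha`, removing the
#' most extreme point while the test rejects, up to `floor(n/10)` removals.
#' Every removal is logged with the observed statistic and critical value.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Significance level per step (default 0.05).
#' @return List: `flags` (logical, `TRUE` = outlier), `values_clean`, and
#'   `log` (tibble: step, index, value, g_statistic, g_critical).
#' @export
detect_outliers <- function(values, alpha = 0.05) {
  n0 <- length(values)
  if (n0 < 3) abort("need n >= 3.")
  max_remove <- floor(n0 / 10)
  flags <- rep(FALSE, n0)
  log_rows <- list()
  for (step in seq_len(max(max_remove, 0))) {
    active <- which(!flags)
    x <- values[active]
    n <- length(x)
    if (n < 3 || sd(x) == 0) break
    z <- abs(x - mean(x)) / sd(x)
    g <- max(z)
    crit <- grubbs_critical(n, alpha)
    if (g <= crit) break
    worst <- active[which.max(z)]
    flags[worst] <- TRUE
    log_rows[[step]] <- tibble(step = step, index = worst,
                               value = values[worst],
                               g_statistic = g, g_critical = crit)
  }
  list(
    flags = flags,
    values_clean = values[!flags],
    log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
      tibble(step = integer(), index = integer(), value = numeric(),
             g_statistic = numeric(), g_critical = numeric())
  )
}
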