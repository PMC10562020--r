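# Cross-network statistical comparison: per network and metric, paired
# differences against a baseline on a shared test set, a closed-form paired
# t-test (two-tailed, df = n - 1), and a D'Agostino-Pearson omnibus
# normality check on each result population.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino) and kurtosis
#' (Anscombe-Glynn) into `K2 = Z1^2 + Z2^2`, referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires n >= 8.
#'
#' @param x numeric vector.
#' @return List with `k2`, `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("n >= 8 required for the omnibus normality test")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(list(k2 = NA_real_, p_value = NA_real_,
                           z_skew = NA_real_, z_kurt = NA_real_))
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Paired t-test, closed form
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a two-tailed
#' p-value. Zero-variance differences are flagged degenerate rather than
#' evaluated.
#'
#' @param d vector of paired differences.
#' @return List with `t`, `df`, `p_value`, `mean`, `degenerate`.
#' @export
paired_t <- function(d) {
  n <- length(d)
  if (n < 2) stop("need at least two paired differences")
  s <- sd(d)
  if (s == 0) {
    return(list(t = NA_real_, df = n - 1L, p_value = NA_real_,
                mean = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p_value = 2 * pt(-abs(t), df = n - 1),
       mean = mean(d), degenerate = FALSE)
}

#' Compare K networks against a baseline
#'
#' For every network and metric, subtracts the baseline's per-scan results
#' from the network's (the error matrix), then reports the mean error, a
#' paired t with `df = n_test - 1`, its two-tailed p-value, and the
#' D'Agostino-Pearson normality p of the network's result population.
#' Normality failures are reported, not used to gate the t-test. A
#' Bonferroni-adjusted p-value column is emitted for information only; the
#' protocol itself applies no multiple-testing correction.
#'
#' @param reports data.frame from [evaluate_masks()] stacked over methods;
#'   must contain every network and the baseline on the same scans.
#' @param baseline value of `method` identifying the baseline rows.
#' @param metrics metric columns to compare.
#' @return data.frame: `network`, `metric`, `n`, `mean_error`, `t`, `df`,
#'   `p_value`, `normality_p`, `p_bonferroni`, `degenerate`.
#' @export
compare_networks <- function(reports, baseline = "baseline",
                             metrics = c("dice", "tpr_paper", "msd_mm",
                                         "mhd_mm")) {
  stopifnot(baseline %in% reports$method)
  nets <- setdiff(unique(reports$method), baseline)
  base <- reports[reports$method == baseline, ]
  base <- base[order(base$scan), ]
  rows <- list()
  for (net in nets) {
    r <- reports[reports$method == net, ]
    r <- r[order(r$scan), ]
    if (!identical(r$scan, base$scan)) {
      stop("network ", net, " and baseline were not evaluated on the same ",
           "scans")
    }
    for (mt in metrics) {
      d <- r[[mt]] - base[[mt]]
      tt <- paired_t(d)
      norm_p <- if (length(r[[mt]]) >= 8 && sd(r[[mt]]) > 0) {
        dagostino_pearson(r[[mt]])$p_value
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        network = net, metric = mt, n = length(d), mean_error = tt$mean,
        t = tt$t, df = tt$df, p_value = tt$p_value, normality_p = norm_p,
        degenerate = tt$degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  out
}
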