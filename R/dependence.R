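#' Sample autocorrelation function
#'
#' Standard biased-denominator sample ACF:
#' `gamma(k) = (1/n) * sum_{t=1}^{n-k} (X_t - Xbar)(X_{t+k} - Xbar)` with the
#' full-series mean in both factors, and `rho(k) = gamma(k) / gamma(0)`.
#'
#' @param series numeric series, `n >= 2`, non-constant.
#' @param max_lag largest lag, `< n`.
#' @return an object of class `acf_result`: fields `n`, `lags` (1..max_lag),
#'   `rho`, `gamma0`.
#' @examples
#' sample_acf(c(1, 2, 3, 4), 3)$rho  # 0.25 -0.30 -0.45
#' @export
sample_acf <- function(series, max_lag) {
  n <- length(series)
  stopifnot(n >= 2, max_lag >= 1, max_lag < n, all(is.finite(series)))
  xc <- series - mean(series)
  gamma0 <- sum(xc^2) / n
  if (gamma0 == 0) stop("degenerate (constant) series: zero variance")
  rho <- vapply(seq_len(max_lag), function(k)
    sum(xc[seq_len(n - k)] * xc[(k + 1):n]) / n / gamma0, numeric(1))
  structure(list(n = n, lags = seq_len(max_lag), rho = rho, gamma0 = gamma0),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat("Sample ACF: n =", x$n, ", lags 1..", max(x$lags), "\n")
  print(setNames(signif(x$rho, 4), paste0("lag", x$lags)))
  invisible(x)
}

#' Per-lag Yule test for autocorrelation
#'
#' Under the iid null, `sqrt(n) * rho_hat(k)` is asymptotically standard
#' normal at every lag, so lag `k` is flagged significant iff
#' `|rho_hat(k)| > z_{alpha/2} / sqrt(n)`.  No adjustment is applied across
#' lags within a series.
#'
#' @param acf an [sample_acf()] result.
#' @param alpha significance level.
#' @param window largest lag considered when reporting the maximum
#'   significant lag.
#' @return an object of class `yule_result`: `alpha`, `threshold`,
#'   `significant` (logical per lag), `max_significant_lag` (0 if none
#'   within the window).
#' @export
yule_test <- function(acf, alpha = 0.05, window = 40) {
  stopifnot(inherits(acf, "acf_result"), alpha > 0, alpha < 1)
  threshold <- qnorm(1 - alpha / 2) / sqrt(acf$n)
  significant <- abs(acf$rho) > threshold
  in_window <- acf$lags <= window
  hit <- acf$lags[significant & in_window]
  structure(list(alpha = alpha, threshold = threshold,
                 lags = acf$lags, significant = significant,
                 max_significant_lag = if (length(hit)) max(hit) else 0L),
            class = "yule_result")
}

#' @export
print.yule_result <- function(x, ...) {
  cat("Yule test: threshold ", signif(x$threshold, 5), " (alpha = ", x$alpha,
      "); ", sum(x$significant), " significant lag(s), max ",
      x$max_significant_lag, "\n", sep = "")
  invisible(x)
}

#' Ljung-Box portmanteau test
#'
#' Aggregates squared sample autocorrelations up to lag `m`:
#' `Q = n * (n + 2) * sum_{k=1}^m rho_hat(k)^2 / (n - k)`, compared to a
#' chi-square distribution with `m` degrees of freedom under the iid null.
#'
#' @param acf an [sample_acf()] result with at least `m` lags.
#' @param m maximum lag (`< n`).
#' @return an object of class `ljung_box_result`: `Q`, `m`, `p_value`.
#' @examples
#' ljung_box(sample_acf(c(1, 2, 3, 4), 3), m = 1)  # Q = 0.5
#' @export
ljung_box <- function(acf, m = 40) {
  stopifnot(inherits(acf, "acf_result"))
  if (m >= acf$n) stop("maximum lag m must be smaller than the series length")
  if (m > length(acf$rho)) stop("ACF holds fewer than m lags")
  k <- seq_len(m)
  Q <- acf$n * (acf$n + 2) * sum(acf$rho[k]^2 / (acf$n - k))
  structure(list(Q = Q, m = as.integer(m),
                 p_value = pchisq(Q, df = m, lower.tail = FALSE)),
            class = "ljung_box_result")
}

#' @export
print.ljung_box_result <- function(x, ...) {
  cat("Ljung-Box: Q =", signif(x$Q, 6), "on", x$m, "lags, p =",
      signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Bonferroni adjustment across a family of tests
#'
#' Test `i` rejects iff `p_i < alpha / N`; the family size defaults to the
#' number of p-values supplied (e.g. one Ljung-Box test per subject).
#'
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise significance level.
#' @param N family size.
#' @return logical vector of per-test rejections, attribute `cutoff`.
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05, N = length(p_values)) {
  stopifnot(N >= 1, alpha > 0, alpha < 1,
            all(p_values >= 0 & p_values <= 1))
  structure(p_values < alpha / N, cutoff = alpha / N)
}

#' Variance-to-variance ratio for the mean of a correlated series
#'
#' For a stationary series the variance of the sample mean is
#' `Var(Ybar) = sigma^2 / n * R` with
#' `R = 1 + 2 * sum_k (1 - k/n) * rho_k`.  `R` is the factor by which the
#' naive iid formula `sigma^2 / n` under- (`R > 1`) or over-estimates
#' (`R < 1`) the true variance.
#'
#' @param rho autocorrelation values at the lags in `lags`.
#' @param n series length (>= 2).
#' @param lags positive integer lags (`< n`), one per `rho` value; defaults
#'   to `1..length(rho)`.
#' @param sigma2 optional series variance; if supplied, `var_iid` and
#'   `var_corrected` are populated.
#' @return an object of class `variance_ratio_result`: `R`, `n`, `lags`,
#'   `rho`, `var_iid`, `var_corrected`.
#' @examples
#' variance_ratio_constant(0.05, n = 101)$R   # 6
#' variance_ratio_single(0.5, lag = 20, n = 80)$R  # 1.75
#' @export
variance_ratio <- function(rho, n, lags = seq_along(rho), sigma2 = NULL) {
  stopifnot(n >= 2, length(rho) == length(lags),
            all(abs(rho) <= 1), all(lags >= 1))
  if (any(lags >= n)) stop("every lag must be smaller than n")
  R <- 1 + 2 * sum((1 - lags / n) * rho)
  var_iid <- if (is.null(sigma2)) NA_real_ else sigma2 / n
  structure(list(R = R, n = as.integer(n), lags = as.integer(lags),
                 rho = rho, var_iid = var_iid,
                 var_corrected = var_iid * R),
            class = "variance_ratio_result")
}

#' @rdname variance_ratio
#' @param lag single lag carrying the only nonzero autocorrelation.
#' @export
variance_ratio_single <- function(rho, lag, n, sigma2 = NULL) {
  variance_ratio(rho, n, lags = lag, sigma2 = sigma2)
}

#' @rdname variance_ratio
#' @details With constant autocorrelation `rho` at every lag, `R` reduces to
#'   the closed form `1 + rho * (n - 1)`.
#' @export
variance_ratio_constant <- function(rho, n, sigma2 = NULL) {
  stopifnot(length(rho) == 1)
  variance_ratio(rep(rho, n - 1), n, sigma2 = sigma2)
}

#' @rdname variance_ratio
#' @param acf an [sample_acf()] result.
#' @param mode `"significant"` (default) keeps only the lags flagged by the
#'   Yule test at `alpha`; `"all"` uses every estimated lag.
#' @param alpha Yule level used in `"significant"` mode.
#' @export
variance_ratio_from_acf <- function(acf, mode = c("significant", "all"),
                                    alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(acf, "acf_result"))
  keep <- if (mode == "significant")
    yule_test(acf, alpha = alpha, window = max(acf$lags))$significant
  else rep(TRUE, length(acf$lags))
  out <- variance_ratio(acf$rho[keep], acf$n, lags = acf$lags[keep],
                        sigma2 = acf$gamma0)
  out$mode <- mode
  out
}

#' @export
print.variance_ratio_result <- function(x, ...) {
  cat("Variance-to-variance ratio R =", signif(x$R, 7), "(n =", x$n, ",",
      length(x$lags), "contributing lag(s))\n")
  invisible(x)
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs statistic `G = max |X_i - Xbar| / s` compared with the
#' t-based critical value
#' `(n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))`, `t = t_{alpha/(2n), n-2}`.
#' Intended as a screen for first-stride outliers before series analysis;
#' iterative re-testing after removal is available but off by default, since
#' repeated testing on small samples overcounts outliers.
#'
#' @param series numeric series, `n >= 3`, non-constant.
#' @param alpha significance level.
#' @param iterative if `TRUE`, repeat the test on the reduced series until
#'   no further outlier is found.
#' @return an object of class `grubbs_result`: `G`, `critical`,
#'   `outlier_index` (index into the original series, or `integer(0)`),
#'   `is_outlier`.
#' @examples
#' grubbs_test(c(1, 1.1, 0.9, 10))$outlier_index  # 4
#' @export
grubbs_test <- function(series, alpha = 0.05, iterative = FALSE) {
  n <- length(series)
  stopifnot(n >= 3, alpha > 0, alpha < 1)
  if (sd(series) == 0) stop("degenerate (constant) series")
  run_one <- function(x) {
    nn <- length(x)
    dev <- abs(x - mean(x))
    G <- max(dev) / sd(x)
    tq <- qt(alpha / (2 * nn), df = nn - 2, lower.tail = FALSE)
    crit <- (nn - 1) / sqrt(nn) * sqrt(tq^2 / (nn - 2 + tq^2))
    list(G = G, critical = crit, idx = which.max(dev), reject = G > crit)
  }
  first <- run_one(series)
  flagged <- integer(0)
  if (first$reject) {
    flagged <- first$idx
    if (iterative) {
      remaining <- setdiff(seq_len(n), flagged)
      while (length(remaining) >= 3 && sd(series[remaining]) > 0) {
        res <- run_one(series[remaining])
        if (!res$reject) break
        flagged <- c(flagged, remaining[res$idx])
        remaining <- setdiff(seq_len(n), flagged)
      }
    }
  }
  structure(list(G = first$G, critical = first$critical,
                 outlier_index = flagged, is_outlier = first$reject),
            class = "grubbs_result")
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat("Grubbs test: G =", signif(x$G, 5), "vs critical", signif(x$critical, 5),
      if (x$is_outlier) paste("-> outlier at index",
                              paste(x$outlier_index, collapse = ", "))
      else "-> no outlier", "\n")
  invisible(x)
}

#' Full stride-dependence report for one stiffness series
#'
#' Bundles the sample ACF, the per-lag Yule test, the Ljung-Box test at
#' maximum lag `m`, and the variance-to-variance ratio (from the Yule-
#' significant lags by default) for one per-stride series.
#'
#' @param series a [stiffness_series()] or plain numeric vector.
#' @param alpha significance level for Yule and the variance-ratio lag
#'   selection.
#' @param max_lag maximum Ljung-Box / ACF lag (capped at `n - 1`).
#' @param vr_mode passed to [variance_ratio_from_acf()].
#' @return an object of class `dependence_report` with elements `acf`,
#'   `yule`, `ljung_box`, `variance_ratio`, `n`.
#' @export
dependence_report <- function(series, alpha = 0.05, max_lag = 40,
                              vr_mode = c("significant", "all")) {
  vr_mode <- match.arg(vr_mode)
  x <- if (inherits(series, "stiffness_series")) series$k else as.numeric(series)
  m <- min(max_lag, length(x) - 1)
  a <- sample_acf(x, m)
  structure(list(n = length(x),
                 acf = a,
                 yule = yule_test(a, alpha = alpha, window = max_lag),
                 ljung_box = ljung_box(a, m = m),
                 variance_ratio = variance_ratio_from_acf(a, mode = vr_mode,
                                                          alpha = alpha)),
            class = "dependence_report")
}

#' @export
print.dependence_report <- function(x, ...) {
  cat("Dependence report (n = ", x$n, "):\n", sep = "")
  print(x$yule); print(x$ljung_box); print(x$variance_ratio)
  invisible(x)
}
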