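#' Specification of the latent per-stride stiffness process
#'
#' The per-stride leg stiffness is modelled as a stationary autoregressive
#' process around a positive mean: `k_t = mean_k + z_t` with
#' `z_t = sum_i ar_coeffs[i] * z_{t-i} + e_t`, `e_t ~ N(0, innovation_sd^2)`.
#' With a single coefficient `phi` this is the AR(1) process whose
#' autocorrelation decays geometrically, `rho_k = phi^k` — the simplest
#' process exhibiting the cross-stride dependence the downstream tests are
#' designed to detect.
#'
#' @param mean_k process mean stiffness, N/m (> 0).
#' @param ar_coeffs numeric vector of AR coefficients (possibly empty for
#'   white noise); the AR polynomial must have all roots outside the unit
#'   circle (stationarity), checked here.
#' @param innovation_sd innovation standard deviation, N/m (>= 0).
#' @param n_strides number of strides to generate (>= 1).
#' @param seed integer seed for this process draw.
#' @return an object of class `stiffness_process_spec`.
#' @examples
#' stiffness_process_spec(20000, ar_coeffs = 0.6, innovation_sd = 1000,
#'                        n_strides = 200, seed = 1)
#' @export
stiffness_process_spec <- function(mean_k = 20000, ar_coeffs = numeric(),
                                   innovation_sd = 1000, n_strides = 100,
                                   seed = 1L) {
  stopifnot(is.numeric(mean_k), length(mean_k) == 1, mean_k > 0,
            is.numeric(ar_coeffs),
            is.numeric(innovation_sd), innovation_sd >= 0,
            is.numeric(n_strides), n_strides >= 1,
            n_strides == as.integer(n_strides))
  if (length(ar_coeffs) > 0) {
    roots <- polyroot(c(1, -ar_coeffs))
    if (any(Mod(roots) <= 1 + 1e-12))
      stop("non-stationary AR coefficients: all roots of the AR polynomial ",
           "must lie outside the unit circle")
  }
  structure(list(mean_k = mean_k, ar_coeffs = as.numeric(ar_coeffs),
                 innovation_sd = innovation_sd,
                 n_strides = as.integer(n_strides), seed = as.integer(seed)),
            class = "stiffness_process_spec")
}

#' @export
print.stiffness_process_spec <- function(x, ...) {
  cat("Stiffness process: mean", x$mean_k, "N/m, AR(",
      length(x$ar_coeffs), ") [", paste(signif(x$ar_coeffs, 4), collapse = ", "),
      "], innovation sd", x$innovation_sd, "N/m,", x$n_strides,
      "strides, seed", x$seed, "\n")
  invisible(x)
}

#' Draw a per-stride stiffness series from its process specification
#'
#' Simulates the stationary AR process via [stats::arima.sim()] (which
#' discards an automatic burn-in so the draw starts in the stationary
#' regime), adds the process mean, and clips any draw below
#' `clip_frac * mean_k` to that floor so every value is a physically usable
#' SLIP stiffness.  Clipping events are counted in the `n_clipped` attribute
#' and reported with a message.
#'
#' @param spec a [stiffness_process_spec()].
#' @param clip_frac lower clip bound as a fraction of `mean_k`.
#' @return numeric vector of length `spec$n_strides`, attribute `n_clipped`.
#' @examples
#' k <- gen_stiffness_series(stiffness_process_spec(
#'   20000, 0.6, 1000, n_strides = 50, seed = 7))
#' length(k)
#' @export
gen_stiffness_series <- function(spec, clip_frac = 0.1) {
  stopifnot(inherits(spec, "stiffness_process_spec"))
  z <- with_seed(spec$seed, {
    if (spec$innovation_sd == 0) {
      rep(0, spec$n_strides)     # degenerate noiseless process
    } else if (length(spec$ar_coeffs) == 0 || all(spec$ar_coeffs == 0)) {
      rnorm(spec$n_strides, 0, spec$innovation_sd)
    } else {
      as.numeric(arima.sim(model = list(ar = spec$ar_coeffs),
                           n = spec$n_strides, sd = spec$innovation_sd))
    }
  })
  k <- spec$mean_k + z
  floor_k <- clip_frac * spec$mean_k
  clipped <- k < floor_k
  if (any(clipped)) {
    message(sum(clipped), " stiffness draw(s) clipped at ", floor_k, " N/m")
    k[clipped] <- floor_k
  }
  attr(k, "n_clipped") <- sum(clipped)
  k
}

#' Measurement noise specification for synthetic trials
#'
#' Gaussian white noise added to every marker coordinate channel and to the
#' force channel, after the noiseless trial (and its ground truth) has been
#' assembled.
#'
#' @param marker_sd marker coordinate noise sd, m.
#' @param force_sd vertical force noise sd, N.
#' @param seed integer seed for the noise draw.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(marker_sd = 0.001, force_sd = 5, seed = 1L) {
  stopifnot(is.numeric(marker_sd), marker_sd >= 0,
            is.numeric(force_sd), force_sd >= 0)
  structure(list(marker_sd = marker_sd, force_sd = force_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}
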