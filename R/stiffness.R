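#' Leg compression over one stance phase
#'
#' The effective leg-spring compression combines the vertical centre-of-mass
#' excursion with a geometric correction for the horizontal sweep of the CoM
#' over the pinned foot:
#' `dL = max(y) - min(y) + l0 * (1 - sqrt(1 - ((max(x) - min(x)) / (2*l0))^2))`,
#' with all coordinates taken after recentring to the world frame.
#'
#' @param stance a [stance_phase()].
#' @param l0 leg rest length, m.
#' @return compression `dL`, m.
#' @examples
#' s <- stance_phase(0, c(0, 3), x = c(-0.15, 0, 0.15),
#'                   y = c(1.0, 0.95, 1.0), F_y = c(100, 1500, 100))
#' leg_compression(s, l0 = 1)
#' @export
leg_compression <- function(stance, l0) {
  stopifnot(inherits(stance, "stance_phase"), is.numeric(l0), l0 > 0)
  sweep <- max(stance$x) - min(stance$x)
  if (sweep > 2 * l0)
    stop("horizontal CoM sweep (", signif(sweep, 4), " m) exceeds 2*l0; ",
         "negative radicand in the compression geometry")
  (max(stance$y) - min(stance$y)) +
    l0 * (1 - sqrt(1 - (sweep / (2 * l0))^2))
}

# first index attaining the minimum CoM height (tie-break: first)
argmin_y <- function(stance) which.min(stance$y)[1]

# Stance-local horizontal coordinate measured from the estimated foot point.
# The planted foot is unobservable from pelvis kinematics.  The default
# ("fit") treats the foot x as a nuisance parameter and profiles it out of
# the no-intercept least-squares fit: for a candidate foot position the
# residual sum of squares after fitting k is
# sum(r^2) - sum(r*p)^2 / sum(p^2), minimised over the x sweep of the CoM
# (the CoM passes over the planted foot during stance).  "argmin_y" places
# the foot below the CoM at its lowest point (exact for a symmetric bounce),
# "midrange" at the midpoint of the x sweep, "none" leaves x untouched.
stance_local_x <- function(stance, foot = c("fit", "argmin_y", "midrange", "none"),
                           l0 = NULL, response = NULL) {
  foot <- match.arg(foot)
  if (foot == "fit") {
    stopifnot(!is.null(l0), !is.null(response))
    rss <- function(xf) {
      L <- sqrt((stance$x - xf)^2 + stance$y^2)
      p <- stance$y * (l0 / L - 1)
      sp2 <- sum(p^2)
      if (sp2 == 0) return(sum(response^2))
      sum(response^2) - sum(response * p)^2 / sp2
    }
    xf <- stats::optimize(rss, range(stance$x), tol = 1e-9)$minimum
    return(stance$x - xf)
  }
  switch(foot,
         argmin_y = stance$x - stance$x[argmin_y(stance)],
         midrange = stance$x - (max(stance$x) + min(stance$x)) / 2,
         none = stance$x)
}

# weight correction conventions for the force entering a stiffness estimate
apply_weight_correction <- function(F, mass, g,
                                    correction = c("subtract", "add", "none")) {
  correction <- match.arg(correction)
  switch(correction,
         subtract = F - mass * g,
         add = F + mass * g,
         none = F)
}

#' Peak-force / compression leg stiffness (k_max)
#'
#' The biologically-motivated estimate: the leg-spring force at the lowest
#' centre-of-mass height, corrected for body weight, divided by the leg
#' compression [leg_compression()].
#'
#' @param stance a [stance_phase()].
#' @param l0 leg rest length, m.
#' @param mass body mass, kg.
#' @param weight_correction how the vertical force at min(y) is corrected
#'   for body weight: `"subtract"` (default, `F - m*g`), `"add"`, or
#'   `"none"`.  The convention used is recorded in the result attributes.
#' @param g gravitational acceleration, m/s^2.
#' @return stiffness, N/m, with attributes `delta_L` and `F_leg`.
#' @export
k_max <- function(stance, l0, mass,
                  weight_correction = c("subtract", "add", "none"), g = 9.81) {
  weight_correction <- match.arg(weight_correction)
  dL <- leg_compression(stance, l0)
  if (dL <= 0)
    stop("undefined stiffness: zero leg compression over the stance")
  i <- argmin_y(stance)
  if (i == 1 || i == length(stance$y))
    warning("min(y) at the stance boundary; possibly truncated stance")
  F_leg <- apply_weight_correction(stance$F_y[i], mass, g, weight_correction)
  structure(F_leg / dL, delta_L = dL, F_leg = F_leg,
            weight_correction = weight_correction)
}

# shared no-intercept least-squares slope of response on the spring-mass
# model predictor p_t = y_t * (l0 / sqrt(x_t^2 + y_t^2) - 1)
ols_slope <- function(stance, l0, response, foot) {
  if (length(stance$y) < 2)
    stop("undefined stiffness: stance has fewer than 2 samples")
  xc <- stance_local_x(stance, foot, l0 = l0, response = response)
  L <- sqrt(xc^2 + stance$y^2)
  if (any(L == 0)) stop("degenerate sample with zero leg length")
  p <- stance$y * (l0 / L - 1)
  sp2 <- sum(p^2)
  if (sp2 == 0)
    stop("undefined stiffness: spring-mass predictor identically zero")
  sum(p * response) / sp2
}

#' Least-squares leg stiffness (k_OLS)
#'
#' The data-driven estimate: the slope of a no-intercept ordinary
#' least-squares fit of the weight-added vertical ground reaction force
#' `F_y + m*g` on the spring-mass model predictor
#' `p_t = y_t * (l0 / sqrt(x_t^2 + y_t^2) - 1)`, evaluated per sample over
#' one stance.  The closed-form slope is `sum(p*r) / sum(p^2)`.
#'
#' `x` in the predictor must be measured from the planted foot; see
#' `foot` for how the foot position is estimated from the CoM path.
#'
#' @param stance a [stance_phase()].
#' @param l0 leg rest length, m.
#' @param mass body mass, kg.
#' @param foot stance-local x origin: `"fit"` (default; the foot x is a
#'   nuisance parameter profiled out of the least-squares fit),
#'   `"argmin_y"` (foot below the CoM at its lowest point), `"midrange"`,
#'   or `"none"`.
#' @param g gravitational acceleration, m/s^2.
#' @return stiffness, N/m.
#' @export
k_ols <- function(stance, l0, mass, foot = "fit", g = 9.81) {
  ols_slope(stance, l0, stance$F_y + mass * g, foot)
}

#' Least-squares leg stiffness without the weight term
#'
#' Validation variant of [k_ols()] with the raw `F_y` as the response.  On
#' noiseless SLIP data the force law is exactly `F_y = k * p_t`, so this
#' variant recovers the injected stiffness.
#'
#' @inheritParams k_ols
#' @return stiffness, N/m.
#' @export
k_ols_noweight <- function(stance, l0, mass, foot = "fit", g = 9.81) {
  ols_slope(stance, l0, stance$F_y, foot)
}

#' Per-stride stiffness series for one trial
#'
#' Applies one stiffness estimator to every stance phase of a trial, in
#' temporal order.  Strides where the estimator is undefined are dropped
#' with a reported gap; their stride indices are absent from the result.
#'
#' @param strides list of [stance_phase()] (from [extract_strides()]).
#' @param meta a [subject_meta()] supplying `l0` and `mass`.
#' @param method `"kmax"`, `"kols"` or `"kols_noweight"`.
#' @param velocity treadmill velocity recorded in the series, m/s.
#' @param ... passed to the estimator (e.g. `weight_correction`, `foot`).
#' @return an object of class `stiffness_series`: fields `subject_id`,
#'   `velocity`, `method`, `k`, `stride_index`.
#' @export
stiffness_series <- function(strides, meta,
                             method = c("kmax", "kols", "kols_noweight"),
                             velocity = NA_real_, ...) {
  method <- match.arg(method)
  stopifnot(inherits(meta, "subject_meta"))
  if (length(strides) == 0) stop("no strides supplied")
  est <- switch(method,
                kmax = function(s) k_max(s, meta$l0, meta$mass, ...),
                kols = function(s) k_ols(s, meta$l0, meta$mass, ...),
                kols_noweight = function(s) k_ols_noweight(s, meta$l0, meta$mass, ...))
  k <- numeric(0); idx <- integer(0)
  for (s in strides) {
    val <- tryCatch(as.numeric(est(s)), error = function(e) {
      message("stride ", s$stride_index, " dropped: ", conditionMessage(e))
      NA_real_
    })
    if (!is.na(val)) {
      k <- c(k, val)
      idx <- c(idx, s$stride_index)
    }
  }
  if (length(k) == 0)
    stop("empty stiffness series: every stride failed")
  structure(list(subject_id = meta$subject_id, velocity = velocity,
                 method = method, k = k, stride_index = idx),
            class = "stiffness_series")
}

#' @export
print.stiffness_series <- function(x, ...) {
  cat("Stiffness series (", x$method, "): subject ", x$subject_id, ", ",
      length(x$k), " strides, mean ", signif(mean(x$k), 6), " N/m\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.stiffness_series <- function(x, ...) {
  data.frame(subject_id = x$subject_id, velocity = x$velocity,
             method = x$method, stride_index = x$stride_index, k = x$k)
}
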