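#' Parameters of the planar spring-loaded inverted pendulum (SLIP) model
#'
#' The SLIP model reduces a running body to a point mass bouncing on a
#' massless linear leg spring.  During stance the foot is pinned to the
#' ground, the leg spring (rest length `l0`, the standing height of the
#' centre of mass) pushes the mass along the leg, and gravity acts downward;
#' flight phases are ballistic.  The model is passive and conservative, which
#' makes it a convenient ground truth: the vertical ground reaction force is
#' exactly `k * (l0 - L) * y / L` with `L` the instantaneous leg length.
#'
#' @param mass body mass, kg.
#' @param l0 leg rest length / standing centre-of-mass height, m.
#' @param touchdown_angle leg angle from vertical at touchdown, rad, in
#'   (0, pi/2).
#' @param apex_height apex (highest) centre-of-mass height of the ballistic
#'   flight preceding each touchdown, m; must be at least
#'   `l0 * cos(touchdown_angle)`.
#' @param forward_speed horizontal centre-of-mass speed, m/s.
#' @param g gravitational acceleration, m/s^2.
#' @return an object of class `slip_params`.
#' @examples
#' slip_params(mass = 70, l0 = 1, touchdown_angle = 0.35, apex_height = 1.02)
#' @export
slip_params <- function(mass = 70, l0 = 1.0, touchdown_angle = 0.35,
                        apex_height = 1.02, forward_speed = 3.5, g = 9.81) {
  stopifnot(is.numeric(mass), mass > 0,
            is.numeric(l0), l0 > 0,
            is.numeric(touchdown_angle),
            touchdown_angle > 0, touchdown_angle < pi / 2,
            is.numeric(forward_speed), forward_speed >= 0,
            is.numeric(g), g > 0)
  y_td <- l0 * cos(touchdown_angle)
  if (apex_height < y_td)
    stop("apex_height (", apex_height, ") must be >= l0*cos(touchdown_angle) = ",
         signif(y_td, 6))
  structure(list(mass = mass, l0 = l0, touchdown_angle = touchdown_angle,
                 apex_height = apex_height, forward_speed = forward_speed,
                 g = g),
            class = "slip_params")
}

#' @export
print.slip_params <- function(x, ...) {
  cat("SLIP parameters: mass", x$mass, "kg, l0", x$l0, "m, touchdown angle",
      signif(x$touchdown_angle, 4), "rad, apex", x$apex_height,
      "m, forward speed", x$forward_speed, "m/s\n")
  invisible(x)
}

# Touchdown state from the nominal apex via ballistic flight.  The foot lands
# ahead of the centre of mass, so the CoM sits at x = -l0*sin(theta) relative
# to the foot, at height y = l0*cos(theta), falling.
touchdown_state <- function(params) {
  y_td <- params$l0 * cos(params$touchdown_angle)
  drop_h <- params$apex_height - y_td
  list(x = -params$l0 * sin(params$touchdown_angle),
       y = y_td,
       vx = params$forward_speed,
       vy = -sqrt(2 * params$g * drop_h),
       t_fall = sqrt(2 * drop_h / params$g))
}

#' Simulate one SLIP stance phase
#'
#' Integrates the stance dynamics from touchdown (leg at rest length,
#' descending) to takeoff (leg length back at `l0`) with fixed-step RK4 and
#' bisection event location of the takeoff time to 1e-9 s.  Coordinates are
#' ground-fixed with the foot at the x-origin.
#'
#' @param k leg stiffness for this stance, N/m.
#' @param params a [slip_params()] object.
#' @param dt integration step, s.  The default 1e-4 s keeps the relative
#'   energy drift of the conservative dynamics below 1e-6.
#' @param max_t integration horizon, s; exceeding it (no takeoff) is an
#'   error, as is the mass reaching the ground.
#' @return a list of class `slip_stance` with numeric vectors `t`, `x`, `y`,
#'   `vx`, `vy`, `F_y` (the vertical ground reaction force, N), the stance
#'   `duration` (s) and the `takeoff` state.
#' @examples
#' st <- simulate_stance(20000, slip_params())
#' range(st$F_y)
#' @export
simulate_stance <- function(k, params, dt = 1e-4, max_t = 5) {
  stopifnot(inherits(params, "slip_params"), is.numeric(k), length(k) == 1)
  if (k <= 0) stop("stiffness k must be positive")
  td <- touchdown_state(params)
  m <- .slip_stance_cpp(k, params$mass, params$l0, params$g,
                        td$x, td$y, td$vx, td$vy, dt, max_t)
  n <- nrow(m)
  structure(list(t = m[, "t"], x = m[, "x"], y = m[, "y"],
                 vx = m[, "vx"], vy = m[, "vy"], F_y = m[, "Fy"],
                 k = k, params = params,
                 duration = m[n, "t"],
                 takeoff = list(x = m[n, "x"], y = m[n, "y"],
                                vx = m[n, "vx"], vy = m[n, "vy"])),
            class = "slip_stance")
}

#' @export
print.slip_stance <- function(x, ...) {
  cat("SLIP stance: k =", x$k, "N/m, duration", signif(x$duration, 5),
      "s, peak Fy", signif(max(x$F_y), 5), "N\n")
  invisible(x)
}

#' Total mechanical energy along a simulated stance
#'
#' Kinetic plus gravitational plus elastic energy at every stored sample;
#' constant (up to integration error) for the passive SLIP.
#'
#' @param stance a `slip_stance` object.
#' @return numeric vector of energies, J.
#' @export
stance_energy <- function(stance) {
  p <- stance$params
  L <- sqrt(stance$x^2 + stance$y^2)
  0.5 * p$mass * (stance$vx^2 + stance$vy^2) +
    p$mass * p$g * stance$y +
    0.5 * stance$k * (p$l0 - L)^2
}
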