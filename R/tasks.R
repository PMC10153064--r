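#' Planned movement duration from target distance
#'
#' Empirical scaling of reach duration with distance, \eqn{T_p = 1.712\,
#' d_0^{1/3}} (s with \eqn{d_0} in m).
#'
#' @param d0 target distance (m), > 0.
#' @return Planned duration (s).
#' @export
#' @examples
#' planned_duration(0.2175)  # ~1.03 s
planned_duration <- function(d0) {
  if (any(d0 <= 0)) stop("d0 must be positive")
  1.712 * d0^(1 / 3)
}

#' Minimum-jerk speed profile
#'
#' Normalised bell-shaped speed profile \eqn{v(t) = \frac{1}{T_p}[30 s^4 -
#' 60 s^3 + 30 s^2]} with \eqn{s = t/T_p} for \eqn{t < T_p} and 0
#' afterwards; its integral over the movement is exactly 1.
#'
#' @param t time (s); vectorised.
#' @param T_p planned movement duration (s), > 0.
#' @return Speed profile value (1/s).
#' @export
min_jerk_speed <- function(t, T_p) {
  stopifnot(T_p > 0)
  s <- t / T_p
  ifelse(t >= 0 & t < T_p, (30 * s^4 - 60 * s^3 + 30 * s^2) / T_p, 0)
}

# completed fraction of the reach, the closed-form integral of the profile
min_jerk_fraction <- function(t, T_p) {
  s <- pmin(pmax(t / T_p, 0), 1)
  6 * s^5 - 15 * s^4 + 10 * s^3
}

#' Reaching task
#'
#' A point-to-point reach from the initial endpoint position `x0` to target
#' `x_t`, with planned duration `T_p` (minimum-jerk scaling of the target
#' distance by default), simulation duration `T_max` and success tolerance
#' `eps_tol`.
#'
#' @param x_t numeric(2) target position (m).
#' @param x0 numeric(2) initial endpoint position (m).
#' @param T_p planned movement duration (s); defaults to
#'   [planned_duration()] of the target distance.
#' @param T_max simulation duration (s).
#' @param eps_tol success tolerance (m).
#' @param label optional task label.
#' @return An object of class `reach_task`.
#' @export
reach_task <- function(x_t, x0, T_p = NULL, T_max = 4, eps_tol = 1e-3,
                       label = "") {
  d0 <- sqrt(sum((x_t - x0)^2))
  if (d0 <= 0) stop("target coincides with the initial position")
  if (is.null(T_p)) T_p <- planned_duration(d0)
  structure(list(x_t = as.numeric(x_t), x0 = as.numeric(x0), d0 = d0,
                 T_p = T_p, T_max = T_max, eps_tol = eps_tol, label = label),
            class = "reach_task")
}

#' The four standard reach targets
#'
#' Places targets at distance `d0` from the initial endpoint position in
#' the four cardinal directions of the workspace frame: `right` (+x),
#' `forward` (+y, away from the chest), `left` (-x) and `back` (-y). Under
#' the default arm geometry the forward target lies near the edge of the
#' workspace and requires a nearly straight arm.
#'
#' @param x0 numeric(2) initial endpoint position (m); defaults to the
#'   forward kinematics of the default initial posture.
#' @param d0 target distance (m).
#' @param ... further arguments passed to [reach_task()].
#' @return A named list of four [reach_task()] objects.
#' @export
make_targets <- function(x0 = NULL, d0 = 0.2175, ...) {
  if (is.null(x0)) {
    p <- arm_params()
    x0 <- forward_kinematics(p, p$initial_angles)$x
  }
  dirs <- list(right = c(1, 0), forward = c(0, 1),
               left = c(-1, 0), back = c(0, -1))
  out <- lapply(names(dirs), function(nm)
    reach_task(x0 + d0 * dirs[[nm]], x0, label = nm, ...))
  names(out) <- names(dirs)
  out
}

#' Minimum-jerk trajectory plan for a reach
#'
#' Straight-line planned trajectory \eqn{x_d(t) = x_0 + (x_t - x_0)
#' \int_0^t v(s) ds} with the minimum-jerk speed profile; the endpoint
#' rests at the target for all \eqn{t \ge T_p}.
#'
#' @param task a [reach_task()] object.
#' @return An object of class `trajectory_plan`.
#' @export
trajectory_plan <- function(task) {
  structure(list(x0 = task$x0, x_t = task$x_t, T_p = task$T_p),
            class = "trajectory_plan")
}

#' Planned endpoint position at time t
#' @param plan a [trajectory_plan()] object.
#' @param t time (s).
#' @return numeric(2) position (m).
#' @export
plan_position <- function(plan, t) {
  plan$x0 + (plan$x_t - plan$x0) * min_jerk_fraction(t, plan$T_p)
}

#' Planned endpoint velocity at time t
#' @inheritParams plan_position
#' @return numeric(2) velocity (m/s).
#' @export
plan_velocity <- function(plan, t) {
  (plan$x_t - plan$x0) * min_jerk_speed(t, plan$T_p)
}

# trapezoidal time-average of a sampled series over [t[i0], t[n]]
.trapz_mean <- function(t, y, i0 = 1) {
  n <- length(t)
  if (i0 >= n) return(y[n])
  tt <- t[i0:n]; yy <- y[i0:n]
  sum(diff(tt) * (yy[-length(yy)] + yy[-1]) / 2) / (tt[length(tt)] - tt[1])
}

#' Movement error
#'
#' Time-averaged Euclidean deviation of the endpoint from the planned
#' trajectory over the whole simulation, \eqn{e_{mv} = \frac{1}{T_{max}}
#' \int_0^{T_{max}} \|x_d(t) - x(t)\| dt}, by trapezoidal quadrature at the
#' sampling step.
#'
#' @param t numeric vector of sample times covering \[0, T_max\].
#' @param x n x 2 matrix of endpoint positions (m).
#' @param plan a [trajectory_plan()] object.
#' @return Movement error (m).
#' @export
movement_error <- function(t, x, plan) {
  if (nrow(x) != length(t)) stop("x and t length mismatch")
  xd <- t(vapply(t, function(ti) plan_position(plan, ti), numeric(2)))
  dev <- sqrt(rowSums((xd - x)^2))
  .trapz_mean(t, dev)
}

#' Stabilisation error and first-success time
#'
#' The target is first reached successfully at the first sample time in the
#' stabilisation phase (\eqn{t \ge T_p}) at which the endpoint is within
#' `eps_tol` of the planned position; the stabilisation error averages the
#' deviation from then to the end of the simulation. If the endpoint never
#' comes within tolerance, `t_succ` is set to 0 so that the stabilisation
#' error equals the movement error. (The literal deviation condition also
#' holds trivially at t = 0, where both trajectories start; the search is
#' therefore restricted to the stabilisation phase, which is what "target
#' first reached successfully" means.)
#'
#' @inheritParams movement_error
#' @param eps_tol success tolerance (m).
#' @return A list with `e_st` (m) and `t_succ` (s).
#' @export
stabilisation_error <- function(t, x, plan, eps_tol = 1e-3) {
  if (nrow(x) != length(t)) stop("x and t length mismatch")
  xd <- t(vapply(t, function(ti) plan_position(plan, ti), numeric(2)))
  dev <- sqrt(rowSums((xd - x)^2))
  cand <- which(t >= plan$T_p - 1e-12 & dev <= eps_tol)
  if (length(cand) == 0)
    return(list(e_st = .trapz_mean(t, dev), t_succ = 0))
  i0 <- cand[1]
  list(e_st = .trapz_mean(t, dev, i0), t_succ = t[i0])
}

#' Co-contraction force at each joint
#'
#' Instantaneous co-contraction at a joint is the force exerted
#' simultaneously by its flexor and extensor, quantified as the overlap
#' \eqn{\min(F_{flex} a_{flex}, F_{ext} a_{ext})} of the two instantaneous
#' muscle forces. Returns the per-joint time series, its time average over
#' the simulation, and the average as a percentage of the pair's isometric
#' strength (the weaker muscle's strength by default, the pair mean if
#' `normalise = "mean"`). Averages over the planned phase (\eqn{t < T_p})
#' and stabilisation phase are also reported when `T_p` is given.
#'
#' @param t numeric vector of sample times.
#' @param forces n x 6 matrix of instantaneous muscle forces \eqn{F_{jj}
#'   a_j} (N), muscle order as in [muscle_names()].
#' @param f_max numeric(6) isometric strengths (N) used for normalisation.
#' @param normalise `"min"` (weaker of the pair) or `"mean"`.
#' @param T_p optional planned-phase boundary (s) for the per-phase split.
#' @return A list with `series` (n x 3 matrix, N), `average` (numeric(3),
#'   N), `percent` (numeric(3), % of isometric strength), and when `T_p` is
#'   given, `average_planned` and `average_stabilisation`.
#' @export
co_contraction <- function(t, forces, f_max = muscle_spec()$f_max,
                           normalise = c("min", "mean"), T_p = NULL) {
  normalise <- match.arg(normalise)
  stopifnot(ncol(forces) == 6, nrow(forces) == length(t))
  series <- sapply(1:3, function(k)
    pmin(forces[, 2 * k - 1], forces[, 2 * k]))
  colnames(series) <- c("shoulder", "elbow", "wrist")
  avg <- apply(series, 2, function(y) .trapz_mean(t, y))
  ref <- sapply(1:3, function(k) {
    pair <- f_max[c(2 * k - 1, 2 * k)]
    if (normalise == "min") min(pair) else mean(pair)
  })
  out <- list(series = series, average = avg, percent = 100 * avg / ref)
  if (!is.null(T_p)) {
    ip <- t < T_p
    out$average_planned <- apply(series[ip, , drop = FALSE], 2, function(y)
      .trapz_mean(t[ip], y))
    if (any(!ip)) {
      i0 <- which(!ip)[1]
      out$average_stabilisation <- apply(series, 2, function(y)
        .trapz_mean(t, y, i0))
    }
  }
  out
}
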