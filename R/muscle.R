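#' Muscle model specification
#'
#' Parameters of the six Hill-type muscles: isometric strengths, optimal
#' lengths, force-length (FL) and force-velocity (FV) shape parameters, and
#' the choice of activation dynamics and force-capacity model.
#'
#' Three activation models are supported:
#' \describe{
#'   \item{IAM}{instantaneous activation, \eqn{a = u};}
#'   \item{O1}{the standard first-order nonlinear model
#'     \eqn{A(a,u)\dot a + a = u} with activation/deactivation time
#'     parameters \eqn{\alpha_{act}(0.5 + 1.5a)} and
#'     \eqn{\alpha_{deact}/(0.5 + 1.5a)};}
#'   \item{O3}{a third-order cascade of three first-order equations with
#'     time constants \eqn{\alpha_{1..3}} and nonlinearity coefficients
#'     \eqn{\beta_{1..3}}, which produces an electromechanical-delay-like
#'     lag and rounded twitch peaks.}
#' }
#' Two force-capacity models are supported: `FMAX` (constant,
#' \eqn{F_{jj} = f_{max,j}}) and `FLV` (\eqn{F_{jj} = f_{max,j}
#' f_l(\tilde l_j) f_v(\tilde v_j)}).
#'
#' Optimal lengths are not independently prescribed for this arm; by
#' construction every muscle is at optimal length in the initial posture,
#' and the default `l0` equals the length of the link distal to the
#' muscle's joint, which sets an anatomically plausible scale for the
#' normalised length excursion and contraction speed.
#'
#' @param f_max numeric(6) isometric strengths (N), muscle order as in
#'   [muscle_names()].
#' @param l0 numeric(6) optimal lengths (m).
#' @param v_max maximum contraction speed (optimal lengths per second).
#' @param b numeric(3) FL shape parameters \eqn{(b_1, b_2, b_3)}.
#' @param d numeric(3) FV shape parameters \eqn{(d_1, d_2, d_3)}.
#' @param activation_model one of `"IAM"`, `"O1"`, `"O3"`.
#' @param force_model one of `"FMAX"`, `"FLV"`.
#' @param alpha_O1 numeric(2) O1 time parameters \eqn{(\alpha_{act},
#'   \alpha_{deact})} in s.
#' @param alpha_O3 numeric(3) O3 time constants in s.
#' @param beta_O3 numeric(3) O3 nonlinearity coefficients in (0, 1].
#' @return An object of class `muscle_spec`.
#' @seealso [muscle_variant()] for the five named model variants.
#' @export
muscle_spec <- function(f_max = c(1500, 1500, 1300, 1000, 500, 300),
                        l0 = rep(c(0.32, 0.25, 0.18), each = 2),
                        v_max = 1.6,
                        b = c(1.3, -1.3, 0.53),
                        d = c(4, 1.8, 30.24),
                        activation_model = c("IAM", "O1", "O3"),
                        force_model = c("FMAX", "FLV"),
                        alpha_O1 = c(0.0945, 0.065),
                        alpha_O3 = c(0.018, 0.040, 0.025),
                        beta_O3 = c(0.6, 0.8, 0.7)) {
  activation_model <- match.arg(activation_model)
  force_model <- match.arg(force_model)
  stopifnot(length(f_max) == 6, all(f_max > 0),
            length(l0) == 6, all(l0 > 0), v_max > 0,
            length(b) == 3, length(d) == 3,
            length(alpha_O1) == 2, all(alpha_O1 > 0),
            length(alpha_O3) == 3, all(alpha_O3 > 0),
            length(beta_O3) == 3, all(beta_O3 > 0), all(beta_O3 <= 1))
  structure(list(f_max = f_max, l0 = l0, v_max = v_max, b = b, d = d,
                 activation_model = activation_model,
                 force_model = force_model,
                 alpha_O1 = alpha_O1, alpha_O3 = alpha_O3,
                 beta_O3 = beta_O3),
            class = "muscle_spec")
}

#' The five named muscle-model variants
#'
#' Registry of the five muscle models studied: the reference model `FMAX`
#' (instantaneous activation, constant strength) and the four combinations
#' of first- or third-order activation dynamics with constant or
#' force-length-velocity modulated strength.
#'
#' @param name one of `"FMAX"`, `"FMAX+O1"`, `"FLV+O1"`, `"FMAX+O3"`,
#'   `"FLV+O3"`.
#' @param ... further arguments passed to [muscle_spec()] (parameter
#'   overrides).
#' @return A [muscle_spec()] object.
#' @export
#' @examples
#' muscle_variant("FLV+O3")
muscle_variant <- function(name, ...) {
  reg <- list(
    "FMAX"    = list(activation_model = "IAM", force_model = "FMAX"),
    "FMAX+O1" = list(activation_model = "O1",  force_model = "FMAX"),
    "FLV+O1"  = list(activation_model = "O1",  force_model = "FLV"),
    "FMAX+O3" = list(activation_model = "O3",  force_model = "FMAX"),
    "FLV+O3"  = list(activation_model = "O3",  force_model = "FLV"))
  if (!name %in% names(reg))
    stop("unknown muscle model variant: ", name,
         " (available: ", paste(names(reg), collapse = ", "), ")")
  do.call(muscle_spec, c(reg[[name]], list(...)))
}

#' Names of the five muscle-model variants
#' @return character(5).
#' @export
muscle_variants <- function() c("FMAX", "FMAX+O1", "FLV+O1", "FMAX+O3", "FLV+O3")

#' @export
print.muscle_spec <- function(x, ...) {
  cat(sprintf("muscle_spec: %s activation, %s force capacity\n",
              x$activation_model, x$force_model))
  cat("  f_max (N):", paste(x$f_max, collapse = ", "), "\n")
  cat("  v_max:", x$v_max, "l0/s;  b:", paste(x$b, collapse = ", "),
      ";  d:", paste(x$d, collapse = ", "), "\n")
  invisible(x)
}

#' Force-length curve
#'
#' Active force-length scaling \eqn{f_l(\tilde l) = \exp(-|(\tilde l^{b_2} -
#' 1)/b_3|^{b_1})}, equal to 1 at optimal length and decaying on either
#' side.
#'
#' @param ltilde normalised muscle length \eqn{l / l_0} (> 0); vectorised.
#' @param b numeric(3) shape parameters.
#' @return Dimensionless gain in (0, 1].
#' @export
fl_curve <- function(ltilde, b = c(1.3, -1.3, 0.53)) {
  if (any(ltilde <= 0)) stop("fl_curve requires ltilde > 0")
  exp(-abs((ltilde^b[2] - 1) / b[3])^b[1])
}

#' Force-velocity curve
#'
#' Active force-velocity scaling with a hyperbolic concentric branch
#' \eqn{(1 - \tilde v)/(1 + d_1 \tilde v)} for shortening (\eqn{\tilde v >
#' 0}) and an eccentric branch \eqn{d_2 - (d_2 - 1)(1 + \tilde v)/(1 - d_3
#' \tilde v)} otherwise; continuous with value 1 at \eqn{\tilde v = 0} and
#' zero at \eqn{\tilde v = 1}. Shortening faster than \eqn{v_{max}} is
#' clamped to \eqn{\tilde v = 1}.
#'
#' @param vtilde normalised shortening velocity (positive = shortening);
#'   vectorised.
#' @param d numeric(3) shape parameters.
#' @return Dimensionless gain in \eqn{[0, d_2 + (d_2-1)/d_3)}.
#' @export
fv_curve <- function(vtilde, d = c(4, 1.8, 30.24)) {
  v <- pmin(vtilde, 1)
  ifelse(v > 0,
         (1 - v) / (1 + d[1] * v),
         d[2] - (d[2] - 1) * (1 + v) / (1 - d[3] * v))
}

#' Tangent velocity damping of the force-velocity dependence
#'
#' The force-velocity curve makes active muscle force decrease with
#' shortening speed, which acts on each joint as a velocity damper with
#' coefficient
#' \deqn{D_k = \sum_{j \in k} r_k^2 \, f_{max,j} f_l(\tilde l_j)
#'   \left(-f_v'(\tilde v_j)\right) a_j / (l_{0,j} v_{max}),}
#' summing the flexor and extensor crossing joint \eqn{k}. With strong
#' co-contraction this damping rate can exceed the reciprocal of the
#' simulation step, so the integrator treats it implicitly (see
#' [step_dynamics()]). Returns zero for constant-strength (`FMAX`) muscle
#' models, whose force has no velocity dependence.
#'
#' @param spec a [muscle_spec()] object.
#' @param wrapping_radii numeric(3) moment arms (m).
#' @param ltilde,vtilde numeric(6) normalised muscle kinematics.
#' @param a numeric(6) activation state.
#' @return numeric(3) non-negative damping coefficients (N·m·s/rad).
#' @export
fv_tangent_damping <- function(spec, wrapping_radii, ltilde, vtilde, a) {
  if (spec$force_model == "FMAX") return(c(0, 0, 0))
  d <- spec$d
  v <- pmin(vtilde, 1)
  # -dfv/dv, positive on both branches, zero in the clamped region
  slope <- ifelse(vtilde > 1, 0,
           ifelse(v > 0, (1 + d[1]) / (1 + d[1] * v)^2,
                  (d[2] - 1) * (1 + d[3]) / (1 - d[3] * v)^2))
  per_muscle <- spec$f_max * fl_curve(ltilde, spec$b) * slope * a /
    (spec$l0 * spec$v_max)
  r <- wrapping_radii[.muscle_joint]
  as.numeric(tapply(r^2 * per_muscle, .muscle_joint, sum))
}

#' Muscle force-capacity matrix
#'
#' Diagonal of the 6x6 force-capacity matrix \eqn{F}: constant isometric
#' strengths in `FMAX` mode, or strengths modulated by the force-length and
#' force-velocity curves in `FLV` mode.
#'
#' @param spec a [muscle_spec()] object.
#' @param ltilde,vtilde numeric(6) normalised lengths and shortening
#'   velocities (ignored in `FMAX` mode).
#' @return numeric(6), the diagonal of \eqn{F} (N).
#' @export
force_capacity <- function(spec, ltilde = rep(1, 6), vtilde = rep(0, 6)) {
  if (spec$force_model == "FMAX") return(spec$f_max)
  spec$f_max * fl_curve(ltilde, spec$b) * fv_curve(vtilde, spec$d)
}

#' Initial activation state
#'
#' All activation states at rest (zero), as at the start of every reach.
#'
#' @param a,a1,a2 optional numeric(6) initial values in \[0, 1\].
#' @return An object of class `activation_state` with components `a`
#'   (activation), `a1`, `a2` (intermediate cascade states, used by the O3
#'   model only) and `u_last` (most recent excitation).
#' @export
activation_state <- function(a = rep(0, 6), a1 = rep(0, 6), a2 = rep(0, 6)) {
  stopifnot(length(a) == 6, length(a1) == 6, length(a2) == 6,
            all(a >= 0 & a <= 1), all(a1 >= 0 & a1 <= 1),
            all(a2 >= 0 & a2 <= 1))
  structure(list(a = a, a1 = a1, a2 = a2, u_last = rep(0, 6)),
            class = "activation_state")
}

#' Advance the activation dynamics one time step
#'
#' Maps neural excitation `u` to activation according to the model in
#' `spec`: the instantaneous model copies `u`, the first-order model
#' integrates \eqn{A(a,u)\dot a + a = u} with the phase-dependent time
#' parameter (activation branch when \eqn{u_j > a_j}), and the third-order
#' model integrates the three-equation cascade. Integration is one explicit
#' Euler step of size `dt`; all states are clamped to \[0, 1\] afterwards.
#'
#' @param spec a [muscle_spec()] object.
#' @param state an [activation_state()] object.
#' @param u numeric(6) excitation in \[0, 1\].
#' @param dt time step (s).
#' @return The updated `activation_state`.
#' @export
activation_step <- function(spec, state, u, dt) {
  if (any(u < 0 | u > 1) || any(!is.finite(u)))
    stop("excitation u must lie in [0, 1]")
  a <- state$a
  switch(spec$activation_model,
    IAM = {
      state$a <- u
    },
    O1 = {
      A <- ifelse(u > a,
                  spec$alpha_O1[1] * (0.5 + 1.5 * a),
                  spec$alpha_O1[2] / (0.5 + 1.5 * a))
      state$a <- pmin(pmax(a + dt * (u - a) / A, 0), 1)
    },
    O3 = {
      al <- spec$alpha_O3; be <- spec$beta_O3
      a1 <- state$a1; a2 <- state$a2
      a1n <- a1 + dt * (u - (be[1] + (1 - be[1]) * u) * a1) / al[1]
      a2n <- a2 + dt * (a1 - (be[2] + (1 - be[2]) * a1) * a2) / al[2]
      an <- a + dt * (a2 - (be[3] + (1 - be[3]) * a2) * a) / al[3]
      state$a1 <- pmin(pmax(a1n, 0), 1)
      state$a2 <- pmin(pmax(a2n, 0), 1)
      state$a <- pmin(pmax(an, 0), 1)
    })
  state$u_last <- u
  state
}

#' Twitch response of an activation model
#'
#' Activation time course in response to a unit excitation pulse: \eqn{u =
#' 1} held for `pulse_duration`, then 0. By default both the pulse and the
#' integration step equal the 2-ms simulation step, i.e. the twitch is
#' characterised exactly as the muscle behaves in simulation; `dt` may be
#' refined to study the continuous-time limit of the cascade.
#'
#' @param spec a [muscle_spec()] object (its `activation_model` is used).
#' @param pulse_duration pulse width (s).
#' @param dt integration step (s), at most `pulse_duration`.
#' @param t_end duration of the simulated response (s).
#' @return A data.frame with columns `t` (s, pulse onset at 0) and `a`.
#' @export
twitch_response <- function(spec, pulse_duration = 0.002, dt = 0.002,
                            t_end = 4) {
  stopifnot(pulse_duration > 0, dt > 0, dt <= pulse_duration + 1e-12)
  n <- ceiling(t_end / dt)
  st <- activation_state()
  a <- numeric(n + 1)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    u <- if (t < pulse_duration - 1e-12) 1 else 0
    st <- activation_step(spec, st, rep(u, 6), dt)
    a[i + 1] <- st$a[1]
  }
  data.frame(t = seq(0, by = dt, length.out = n + 1), a = a)
}

#' Twitch characteristics
#'
#' Time-to-peak, peak amplitude and half-relaxation time of the activation
#' twitch produced by a unit excitation pulse.
#'
#' Following the physiological convention for twitch timing, time-to-peak
#' is measured from the *onset* of the twitch -- the moment activation
#' first exceeds `onset_frac` of the peak -- rather than from the stimulus,
#' so the electromechanical-delay-like latency of the third-order cascade
#' (during which activation is essentially zero) is excluded.
#' Half-relaxation is the time from the peak until activation first falls
#' below half the peak. Both crossings are located by linear interpolation
#' between samples.
#'
#' @inheritParams twitch_response
#' @param onset_frac fraction of the peak amplitude defining twitch onset.
#' @return A list with components `time_to_peak` (s, from onset),
#'   `onset_latency` (s, pulse onset to twitch onset), `peak_amplitude`,
#'   `half_relaxation_time` (s).
#' @export
#' @examples
#' twitch_characteristics(muscle_variant("FMAX+O3"))
twitch_characteristics <- function(spec, pulse_duration = 0.002, dt = 0.002,
                                   t_end = 4, onset_frac = 0.01) {
  tr <- twitch_response(spec, pulse_duration, dt, t_end)
  ip <- which.max(tr$a)
  peak <- tr$a[ip]
  thr <- onset_frac * peak
  io <- which(tr$a > thr)[1]
  t_on <- if (io == 1) 0 else
    tr$t[io - 1] + (thr - tr$a[io - 1]) / (tr$a[io] - tr$a[io - 1]) * dt
  below <- which(tr$a < peak / 2 & seq_along(tr$a) > ip)
  if (length(below) == 0)
    stop("activation did not decay below half the peak within t_end")
  ih <- below[1]
  t_half <- tr$t[ih - 1] +
    (tr$a[ih - 1] - peak / 2) / (tr$a[ih - 1] - tr$a[ih]) * dt
  list(time_to_peak = tr$t[ip] - t_on, onset_latency = t_on,
       peak_amplitude = peak, half_relaxation_time = t_half - tr$t[ip])
}

#' Twitch comparison table across activation models
#'
#' Convenience wrapper producing the twitch time courses of the three
#' activation models side by side (for plotting or CSV export).
#'
#' @inheritParams twitch_response
#' @return A data.frame with columns `t`, `IAM`, `O1`, `O3`.
#' @export
twitch_table <- function(pulse_duration = 0.002, dt = 0.002, t_end = 0.5) {
  models <- c("IAM", "O1", "O3")
  out <- NULL
  for (m in models) {
    tr <- twitch_response(muscle_spec(activation_model = m),
                          pulse_duration, dt, t_end)
    if (is.null(out)) out <- data.frame(t = tr$t)
    out[[m]] <- tr$a
  }
  out
}
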