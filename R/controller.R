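#' Feedback control parameters
#'
#' Diagonal proportional and derivative gains of the endpoint-space PD law
#' and the prediction time of the controller's internal forward model.
#'
#' @param Kp numeric(3) position gains (N·m/rad), one per joint.
#' @param Kv numeric(3) velocity gains (N·m·s/rad).
#' @param tau prediction time (s); must be a non-negative integer multiple
#'   of the simulation step `dt`.
#' @param dt simulation step used to validate `tau` (s).
#' @return An object of class `control_params`.
#' @export
control_params <- function(Kp, Kv, tau = 0, dt = 0.002) {
  stopifnot(length(Kp) == 3, length(Kv) == 3, all(Kp >= 0), all(Kv >= 0),
            tau >= 0)
  steps <- tau / dt
  if (abs(steps - round(steps)) > 1e-9)
    stop("tau must be a non-negative integer multiple of dt")
  structure(list(Kp = as.numeric(Kp), Kv = as.numeric(Kv), tau = tau,
                 tau_steps = as.integer(round(steps))),
            class = "control_params")
}

#' @export
print.control_params <- function(x, ...) {
  cat("control_params\n")
  cat("  Kp (N·m/rad):  ", paste(round(x$Kp, 2), collapse = ", "), "\n")
  cat("  Kv (N·m·s/rad):", paste(round(x$Kv, 2), collapse = ", "), "\n")
  cat("  tau (ms):      ", x$tau * 1000, "\n")
  invisible(x)
}

#' Pseudo-inverse of the endpoint Jacobian
#'
#' Moore-Penrose pseudo-inverse \eqn{J^\dagger = J^T (J J^T)^{-1}} of the
#' 2x3 endpoint Jacobian. Near the workspace edge (straight arm) the
#' Jacobian loses row rank; when its smallest singular value drops below
#' `sigma_min` a damped least-squares inverse \eqn{J^T (J J^T + \lambda^2
#' I)^{-1}} is used instead, which prevents torque spikes at the cost of a
#' small bias.
#'
#' @param J 2x3 Jacobian matrix.
#' @param lambda damping factor used near singularity.
#' @param sigma_min smallest-singular-value threshold engaging the damping.
#' @return 3x2 matrix.
#' @export
pinv_jacobian <- function(J, lambda = 1e-3, sigma_min = 1e-2) {
  G <- J %*% t(J)
  # eigenvalues of the symmetric 2x2 Gram matrix -> singular values of J
  tr <- G[1, 1] + G[2, 2]
  dis <- sqrt(max((G[1, 1] - G[2, 2])^2 / 4 + G[1, 2]^2, 0))
  ev_min <- tr / 2 - dis
  if (ev_min < sigma_min^2)
    G <- G + lambda^2 * diag(2)
  det <- G[1, 1] * G[2, 2] - G[1, 2] * G[2, 1]
  Ginv <- matrix(c(G[2, 2], -G[2, 1], -G[1, 2], G[1, 1]), 2, 2) / det
  t(J) %*% Ginv
}

#' Predict the plant state over the controller's horizon
#'
#' Integrates an exact copy of the plant (rigid-body dynamics, activation
#' dynamics and force model) forward `tau_steps` simulation steps with the
#' excitation held constant, as the controller's internal forward model
#' does. With a zero horizon the current state is returned unchanged.
#'
#' @param model an [arm_model()] bundle.
#' @param state an [arm_state()] object.
#' @param act an [activation_state()] object.
#' @param u_held numeric(6) excitation held constant during prediction.
#' @param tau_steps non-negative integer number of `dt` steps.
#' @return A list with the predicted `state`, `act`, endpoint `x`, `xdot`,
#'   Jacobian `J`, and normalised muscle kinematics `ltilde`, `vtilde`.
#' @export
predict_state <- function(model, state, act, u_held, tau_steps) {
  stopifnot(tau_steps >= 0, tau_steps == round(tau_steps))
  for (i in seq_len(tau_steps)) {
    stepped <- plant_step(model, state, act, u_held)
    state <- stepped$state
    act <- stepped$act
  }
  fk <- forward_kinematics(model$params, state$q, state$qdot)
  geo <- muscle_lengths(model$params, model$spec, state$q, state$qdot)
  list(state = state, act = act, x = fk$x, xdot = fk$xdot, J = fk$J,
       ltilde = geo$ltilde, vtilde = geo$vtilde)
}

#' Desired joint torque from endpoint errors
#'
#' PD law mapping endpoint position and velocity errors to joint torques
#' through the (damped) pseudo-inverse of the Jacobian at the predicted
#' configuration: \eqn{T_d = K_p J^\dagger (x_d - \hat x) + K_v J^\dagger
#' (\dot x_d - \hat{\dot x})}.
#'
#' @param ctrl a [control_params()] object.
#' @param x_d,xdot_d desired endpoint position (m) and velocity (m/s).
#' @param x_hat,xdot_hat predicted endpoint position and velocity.
#' @param J Jacobian at the predicted configuration (2x3).
#' @return numeric(3) desired joint torques (N·m).
#' @export
desired_torque <- function(ctrl, x_d, xdot_d, x_hat, xdot_hat, J) {
  Jp <- pinv_jacobian(J)
  as.numeric(ctrl$Kp * (Jp %*% (x_d - x_hat)) +
             ctrl$Kv * (Jp %*% (xdot_d - xdot_hat)))
}

#' Inverse muscle model: excitation from desired torque
#'
#' Converts a desired joint torque into muscle excitations under the
#' no-co-excitation rule: at each joint only the agonist (the muscle whose
#' moment-arm sign matches the torque sign) is excited, with \eqn{u =
#' T_{d,k} / (R_{kj} F_{jj})}, clamped to \[0, 1\] when the demand exceeds
#' the agonist's torque capacity; the antagonist's excitation is exactly
#' zero, as is both muscles' when the demanded torque is zero.
#'
#' @param T_d numeric(3) desired joint torques (N·m).
#' @param R 3x6 moment-arm matrix (see [moment_arm_matrix()]).
#' @param F_diag numeric(6) diagonal of the force-capacity matrix (N),
#'   evaluated at the predicted muscle kinematics.
#' @return numeric(6) excitations in \[0, 1\].
#' @export
excitation_from_torque <- function(T_d, R, F_diag) {
  u <- numeric(6)
  for (k in 1:3) {
    if (T_d[k] > 0) {
      j <- 2 * k - 1  # flexor
      u[j] <- min(T_d[k] / (R[k, j] * F_diag[j]), 1)
    } else if (T_d[k] < 0) {
      j <- 2 * k      # extensor
      u[j] <- min(T_d[k] / (R[k, j] * F_diag[j]), 1)
    }
  }
  u
}

#' One control step
#'
#' Composes the controller: predict the plant state at \eqn{t + \tau} with
#' the previous excitation held, evaluate the planned trajectory at
#' \eqn{t + \tau}, compute the desired torque with the PD law, and invert
#' the muscle model (force capacity evaluated at the predicted muscle
#' kinematics) under the no-co-excitation rule.
#'
#' @param model an [arm_model()] bundle.
#' @param ctrl a [control_params()] object.
#' @param plan a [trajectory_plan()] object.
#' @param state,act current plant state.
#' @param u_prev numeric(6) excitation applied at the previous step (held
#'   during prediction).
#' @param t current time (s).
#' @return numeric(6) excitation u(t).
#' @export
control_step <- function(model, ctrl, plan, state, act, u_prev, t) {
  pred <- predict_state(model, state, act, u_prev, ctrl$tau_steps)
  t_ref <- t + ctrl$tau
  x_d <- plan_position(plan, t_ref)
  xdot_d <- plan_velocity(plan, t_ref)
  T_d <- desired_torque(ctrl, x_d, xdot_d, pred$x, pred$xdot, pred$J)
  F_diag <- force_capacity(model$spec, pred$ltilde, pred$vtilde)
  excitation_from_torque(T_d, model$R, F_diag)
}
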