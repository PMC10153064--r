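#' Arm model parameters
#'
#' Geometry, mass and joint-limit parameters for the planar four-link arm
#' (fixed chest link plus upper arm, forearm and hand, connected by shoulder,
#' elbow and wrist hinge joints moving in the horizontal plane). Defaults are
#' the published reference values for this model; every argument can be
#' overridden individually or through a configuration file (see
#' [read_config()]).
#'
#' Each moving link is modelled as a uniform thin rod (centre of mass at
#' mid-link, moment of inertia \eqn{mL^2/12} about it); only masses and
#' lengths of the links are prescribed, so the rod is the simplest consistent
#' mass distribution. Joint angles are measured relative to the proximal
#' link with flexion positive; the chest link is fixed along the world
#' \eqn{-x} axis with the shoulder at the origin, so the absolute link angles
#' are the cumulative sums of the joint angles measured from \eqn{+x}.
#'
#' @param link_lengths numeric(4), link lengths in m (chest, upper arm,
#'   forearm, hand).
#' @param link_masses numeric(4), link masses in kg.
#' @param wrapping_radii numeric(3), radii in m of the cylindrical wrapping
#'   surfaces at shoulder, elbow and wrist; these set the (constant) muscle
#'   moment arms.
#' @param joint_ranges 2x3 matrix (rows min, max) of feasible joint angles in
#'   radians.
#' @param initial_angles numeric(3), initial joint angles in radians.
#' @param dt simulation time step in s.
#' @param limit_stiffness,limit_damping one-sided spring-damper constants
#'   (N·m/rad and N·m·s/rad) applied outside the feasible joint range.
#' @param limit_width boundary-layer width (rad) over which the limit
#'   spring ramps up to its full stiffness (see [joint_limit_forces()]).
#' @return An object of class `arm_params`.
#' @export
#' @examples
#' p <- arm_params()
#' p$initial_angles * 180 / pi
arm_params <- function(link_lengths = c(0.44, 0.32, 0.25, 0.18),
                       link_masses = c(3.1, 1.9, 1.1, 0.41),
                       wrapping_radii = c(0.045, 0.041, 0.035),
                       joint_ranges = rbind(min = c(-20, 5, -60) * pi / 180,
                                            max = c(120, 120, 70) * pi / 180),
                       initial_angles = c(20, 80, 20) * pi / 180,
                       dt = 0.002,
                       limit_stiffness = 1e4,
                       limit_damping = 1e2,
                       limit_width = 0.5 * pi / 180) {
  stopifnot(length(link_lengths) == 4, all(link_lengths > 0),
            length(link_masses) == 4, all(link_masses > 0),
            length(wrapping_radii) == 3, all(wrapping_radii > 0),
            is.matrix(joint_ranges), dim(joint_ranges) == c(2, 3),
            length(initial_angles) == 3, dt > 0,
            limit_stiffness >= 0, limit_damping >= 0, limit_width > 0)
  if (any(joint_ranges[1, ] >= joint_ranges[2, ]))
    stop("joint_ranges must satisfy min < max for every joint")
  if (any(initial_angles < joint_ranges[1, ] | initial_angles > joint_ranges[2, ]))
    stop("initial_angles must lie inside joint_ranges")

  p <- list(link_lengths = link_lengths, link_masses = link_masses,
            wrapping_radii = wrapping_radii, joint_ranges = joint_ranges,
            initial_angles = initial_angles, dt = dt,
            limit_stiffness = limit_stiffness, limit_damping = limit_damping,
            limit_width = limit_width)

  # precomputed rigid-body constants (moving links only)
  L <- link_lengths[2:4]
  m <- link_masses[2:4]
  d <- matrix(0, 3, 3)  # d[i, k]: lever of absolute angle k in COM of link i
  d[1, 1] <- L[1] / 2
  d[2, 1] <- L[1]; d[2, 2] <- L[2] / 2
  d[3, 1] <- L[1]; d[3, 2] <- L[2]; d[3, 3] <- L[3] / 2
  A <- matrix(0, 3, 3)
  for (k in 1:3) for (l in 1:3)
    A[k, l] <- sum(m * d[, k] * d[, l])
  p$.A <- A
  p$.Irot <- m * L^2 / 12
  p$.L <- L
  # lower-triangular ones mapping relative to absolute angles, theta = Lm q
  p$.Lm <- lower.tri(diag(3), diag = TRUE) * 1
  class(p) <- "arm_params"
  p
}

#' @export
print.arm_params <- function(x, ...) {
  cat("Planar 3-joint arm parameters\n")
  cat("  link lengths (m):   ", paste(x$link_lengths, collapse = ", "), "\n")
  cat("  link masses (kg):   ", paste(x$link_masses, collapse = ", "), "\n")
  cat("  wrapping radii (m): ", paste(x$wrapping_radii, collapse = ", "), "\n")
  cat("  initial angles (deg):",
      paste(round(x$initial_angles * 180 / pi, 1), collapse = ", "), "\n")
  cat("  dt (s):             ", x$dt, "\n")
  invisible(x)
}

#' Arm state
#'
#' Joint-space state of the arm: joint angles `q` (rad), joint velocities
#' `qdot` (rad/s) and simulation time `t` (s).
#'
#' @param q numeric(3) joint angles in rad.
#' @param qdot numeric(3) joint angular velocities in rad/s.
#' @param t time in s.
#' @return An object of class `arm_state`.
#' @export
arm_state <- function(q, qdot = c(0, 0, 0), t = 0) {
  stopifnot(length(q) == 3, length(qdot) == 3, is.finite(c(q, qdot, t)))
  structure(list(q = as.numeric(q), qdot = as.numeric(qdot), t = t),
            class = "arm_state")
}

#' @export
print.arm_state <- function(x, ...) {
  cat(sprintf("arm_state at t = %.4f s\n", x$t))
  cat("  q    (deg):  ", paste(round(x$q * 180 / pi, 3), collapse = ", "), "\n")
  cat("  qdot (deg/s):", paste(round(x$qdot * 180 / pi, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Joint-space inertia matrix
#'
#' Configuration-dependent inertia matrix \eqn{M(q)} of the three moving
#' links, expressed in relative joint coordinates. Built from the
#' absolute-angle inertia of uniform-rod links and mapped through the linear
#' relation between relative and absolute angles.
#'
#' @param params an [arm_params()] object.
#' @param q numeric(3) joint angles (rad).
#' @return A symmetric positive definite 3x3 matrix (kg·m^2).
#' @export
inertia_matrix <- function(params, q) {
  stopifnot(is.finite(q), length(q) == 3)
  th <- cumsum(q)
  cd <- cos(outer(th, th, "-"))
  Mabs <- params$.A * cd
  diag(Mabs) <- diag(Mabs) + params$.Irot
  M <- crossprod(params$.Lm, Mabs %*% params$.Lm)
  (M + t(M)) / 2
}

#' Coriolis and centrifugal joint torques
#'
#' Velocity-dependent bias torques \eqn{c(q, \dot q)} of the arm's equation
#' of motion \eqn{M \ddot q + c - f_c = T}. Quadratic in the joint
#' velocities and identically zero at rest.
#'
#' @inheritParams inertia_matrix
#' @param qdot numeric(3) joint angular velocities (rad/s).
#' @return numeric(3) joint torques (N·m).
#' @export
bias_forces <- function(params, q, qdot) {
  stopifnot(is.finite(q), is.finite(qdot))
  th <- cumsum(q)
  thd <- cumsum(qdot)
  sd <- sin(outer(th, th, "-"))
  cabs <- as.numeric((params$.A * sd) %*% (thd^2))
  rev(cumsum(rev(cabs)))
}

#' Joint-limit constraint torques
#'
#' One-sided spring-damper torques engaging only outside the feasible joint
#' range: zero on the interior, and a restoring torque (plus damping)
#' beyond either bound. The spring force ramps in smoothly over a small
#' boundary layer (`limit_width`, default 0.5 degrees): the stiffness seen
#' immediately at the bound is zero and grows to the full
#' `limit_stiffness` beyond the layer, i.e. \eqn{f = -k\,p^2/(p + w)} for
#' penetration \eqn{p}. A hard on/off spring would make the force
#' discontinuous in time at the engagement boundary and sustain
#' discretization-scale chatter when the controller holds a joint against
#' its bound; the smooth onset mimics the graded soft constraints of
#' general-purpose physics engines.
#'
#' @inheritParams bias_forces
#' @return numeric(3) constraint torques (N·m), entering the equation of
#'   motion as \eqn{+f_c} on the torque side.
#' @export
joint_limit_forces <- function(params, q, qdot) {
  stopifnot(is.finite(q), is.finite(qdot))
  lo <- params$joint_ranges[1, ]
  hi <- params$joint_ranges[2, ]
  w <- params$limit_width
  pen <- pmax(q - hi, 0) + pmin(q - lo, 0)
  engaged <- pen != 0
  fc <- numeric(3)
  ap <- abs(pen[engaged])
  fc[engaged] <- -params$limit_stiffness * sign(pen[engaged]) *
    ap^2 / (ap + w) - params$limit_damping * qdot[engaged]
  fc
}

#' Muscle moment-arm matrix
#'
#' The constant 3x6 matrix \eqn{R} mapping the six muscle forces to joint
#' torques, \eqn{T = R F a}. Each agonist-antagonist pair crosses a single
#' joint over a cylindrical wrapping surface, so each column has exactly one
#' nonzero entry: \eqn{+r_k} for the flexor of joint \eqn{k}, \eqn{-r_k} for
#' its extensor. Muscles are ordered (shoulder flexor, shoulder extensor,
#' elbow flexor, elbow extensor, wrist flexor, wrist extensor).
#'
#' @inheritParams inertia_matrix
#' @return 3x6 numeric matrix (m).
#' @export
moment_arm_matrix <- function(params) {
  r <- params$wrapping_radii
  R <- matrix(0, 3, 6)
  for (k in 1:3) {
    R[k, 2 * k - 1] <- r[k]
    R[k, 2 * k] <- -r[k]
  }
  rownames(R) <- c("shoulder", "elbow", "wrist")
  colnames(R) <- muscle_names()
  R
}

#' Muscle names in canonical order
#' @return character(6).
#' @export
muscle_names <- function() {
  c("shoulder_flexor", "shoulder_extensor",
    "elbow_flexor", "elbow_extensor",
    "wrist_flexor", "wrist_extensor")
}

# signed moment arm per muscle (+flexor, -extensor) and joint index per muscle
.muscle_signs <- rep(c(1, -1), 3)
.muscle_joint <- rep(1:3, each = 2)

#' Normalised muscle lengths and contraction velocities
#'
#' With constant moment arms, the length of muscle \eqn{j} crossing joint
#' \eqn{k} is \eqn{l_j = l_{0,j} - s_j r_k (q_k - q_k(0))} with \eqn{s_j =
#' +1} for flexors and \eqn{-1} for extensors, so every muscle is at its
#' optimal length in the initial posture. The normalised contraction speed
#' \eqn{\tilde v = -\dot l / (l_0 v_{max})} is positive during shortening.
#'
#' @inheritParams bias_forces
#' @param spec a [muscle_spec()] object supplying \eqn{l_0} and
#'   \eqn{v_{max}}.
#' @return A list with numeric(6) components `l` (m), `ltilde`, `vtilde`.
#' @export
muscle_lengths <- function(params, spec, q, qdot) {
  r <- params$wrapping_radii[.muscle_joint]
  dq <- (q - params$initial_angles)[.muscle_joint]
  l <- spec$l0 - .muscle_signs * r * dq
  if (any(l <= 0))
    stop("non-positive muscle length; check l0 / wrapping radii parameterisation")
  vtilde <- .muscle_signs * r * qdot[.muscle_joint] / (spec$l0 * spec$v_max)
  list(l = l, ltilde = l / spec$l0, vtilde = vtilde)
}

#' Forward kinematics of the hand endpoint
#'
#' Position and velocity of the distal tip of the hand link in the
#' horizontal plane, and the 2x3 endpoint Jacobian \eqn{J(q)} with
#' \eqn{\dot x = J \dot q}.
#'
#' @inheritParams bias_forces
#' @return A list with components `x` (numeric(2), m), `xdot` (numeric(2),
#'   m/s) and `J` (2x3 matrix).
#' @export
forward_kinematics <- function(params, q, qdot = c(0, 0, 0)) {
  stopifnot(is.finite(q), is.finite(qdot))
  th <- cumsum(q)
  u <- params$.L * cos(th)
  v <- params$.L * sin(th)
  x <- c(sum(u), sum(v))
  # J[, k] = sum_{i >= k} L_i (-sin th_i, cos th_i)
  Su <- rev(cumsum(rev(u)))
  Sv <- rev(cumsum(rev(v)))
  J <- rbind(-Sv, Su)
  dimnames(J) <- NULL
  list(x = x, xdot = as.numeric(J %*% qdot), J = J)
}

# 3x3 linear solve by cofactor expansion (hot path; avoids solve() overhead)
.solve3 <- function(M, b) {
  a11 <- M[1]; a21 <- M[2]; a31 <- M[3]
  a12 <- M[4]; a22 <- M[5]; a32 <- M[6]
  a13 <- M[7]; a23 <- M[8]; a33 <- M[9]
  c11 <- a22 * a33 - a23 * a32
  c12 <- a13 * a32 - a12 * a33
  c13 <- a12 * a23 - a13 * a22
  det <- a11 * c11 + a21 * c12 + a31 * c13
  c21 <- a23 * a31 - a21 * a33
  c22 <- a11 * a33 - a13 * a31
  c23 <- a13 * a21 - a11 * a23
  c31 <- a21 * a32 - a22 * a31
  c32 <- a12 * a31 - a11 * a32
  c33 <- a11 * a22 - a12 * a21
  c(c11 * b[1] + c12 * b[2] + c13 * b[3],
    c21 * b[1] + c22 * b[2] + c23 * b[3],
    c31 * b[1] + c32 * b[2] + c33 * b[3]) / det
}

#' Advance the arm dynamics one time step
#'
#' Solves the equation of motion \eqn{M(q)\ddot q + c(q,\dot q) - f_c(q) =
#' T} for the joint accelerations and integrates one step of size
#' `params$dt` with the semi-implicit Euler scheme (velocity updated first,
#' position with the new velocity). The plane is horizontal, so gravity does
#' not enter.
#'
#' Whenever a joint is outside its feasible range the one-sided
#' spring-damper limit torque is folded into the velocity update
#' implicitly (spring evaluated at the end-of-step position, damper at the
#' end-of-step velocity), which keeps the stiff limit constraint stable at
#' the 2-ms step; on the interior of the feasible range the update is the
#' plain semi-implicit Euler step.
#'
#' `joint_damping` carries any velocity-derivative of the applied torques
#' (in this model, the tangent damping of the muscles' force-velocity
#' dependence, see [fv_tangent_damping()]); it is likewise treated
#' implicitly in the velocity update. With active, co-contracting FLV
#' muscles the force-velocity slope can damp the wrist at rates above
#' 1/dt, where an explicit evaluation oscillates at the discretization
#' scale; the implicit treatment integrates the same continuous dynamics
#' stably.
#'
#' @inheritParams inertia_matrix
#' @param state an [arm_state()] object.
#' @param torque numeric(3) joint torques \eqn{T} (N·m).
#' @param joint_damping numeric(3) non-negative velocity-damping
#'   coefficients (N·m·s/rad) treated implicitly.
#' @return The `arm_state` at `t + dt`.
#' @export
step_dynamics <- function(params, state, torque,
                          joint_damping = c(0, 0, 0)) {
  if (!all(is.finite(state$q)) || !all(is.finite(state$qdot)))
    stop("non-finite arm state (numerical blow-up)")
  stopifnot(is.finite(torque), length(torque) == 3)
  dt <- params$dt
  q <- state$q
  qd <- state$qdot
  M <- inertia_matrix(params, q)
  rhs <- torque - bias_forces(params, q, qd)

  lo <- params$joint_ranges[1, ]
  hi <- params$joint_ranges[2, ]
  pen <- pmax(q - hi, 0) + pmin(q - lo, 0)  # signed penetration depth
  engaged <- pen != 0
  damp <- joint_damping
  if (any(engaged)) {
    # implicit spring-damper with the smooth-onset spring of
    # joint_limit_forces(): force term at the current penetration, tangent
    # stiffness and damper taken at the end-of-step velocity
    k <- params$limit_stiffness
    b <- params$limit_damping
    w <- params$limit_width
    ap <- abs(pen)
    rhs <- rhs - k * sign(pen) * ap^2 / (ap + w)
    kt <- k * (ap^2 + 2 * ap * w) / (ap + w)^2  # tangent stiffness
    damp <- damp + engaged * (b + kt * dt)
  }
  if (any(damp > 0)) {
    Meff <- M
    diag(Meff) <- diag(Meff) + dt * damp
    qdot <- .solve3(Meff, as.numeric(M %*% qd) + dt * rhs)
  } else {
    qdot <- qd + dt * .solve3(M, rhs)
  }
  arm_state(q + dt * qdot, qdot, state$t + dt)
}
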