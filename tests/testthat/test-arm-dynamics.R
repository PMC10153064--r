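test_that("arm_params validates geometry and defaults to the reference arm", {
  p <- arm_params()
  expect_equal(p$link_lengths, c(0.44, 0.32, 0.25, 0.18))
  expect_equal(p$link_masses, c(3.1, 1.9, 1.1, 0.41))
  expect_equal(p$wrapping_radii, c(0.045, 0.041, 0.035))
  expect_equal(p$initial_angles, c(20, 80, 20) * pi / 180)
  expect_equal(p$dt, 0.002)
  expect_error(arm_params(link_lengths = c(0, 0.3, 0.2, 0.1)))
  expect_error(arm_params(initial_angles = c(3, 0.5, 0.5)),
               "inside joint_ranges")
  expect_error(arm_params(joint_ranges = rbind(c(1, 0, 0), c(0, 1, 1))),
               "min < max")
})

test_that("inertia matrix is symmetric positive definite across the workspace", {
  set.seed(1)
  for (i in 1:2000) {
    M <- inertia_matrix(default_params, random_q())
    expect_identical(M, t(M))
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("inertia matrix matches the kinetic-energy Hessian oracle", {
  qs <- list(default_params$initial_angles,
             c(0.1, 0.9, -0.4), c(1.5, 1.2, 0.8))
  for (q in qs) {
    M <- inertia_matrix(default_params, q)
    expect_equal(M, inertia_oracle(q), tolerance = 1e-8)
  }
})

test_that("bias forces are quadratic in velocity and match the Lagrangian oracle", {
  set.seed(2)
  expect_equal(bias_forces(default_params, random_q(), c(0, 0, 0)),
               c(0, 0, 0))
  for (i in 1:20) {
    q <- random_q()
    qd <- rnorm(3)
    c1 <- bias_forces(default_params, q, qd)
    expect_equal(bias_forces(default_params, q, 2 * qd), 4 * c1,
                 tolerance = 1e-12)
    expect_equal(c1, bias_oracle(q, qd), tolerance = 1e-6)
  }
})

test_that("joint limit torques vanish inside the range and push back outside", {
  set.seed(3)
  for (i in 1:50)
    expect_identical(joint_limit_forces(default_params, random_q(), rnorm(3)),
                     c(0, 0, 0))
  hi <- default_params$joint_ranges[2, ]
  q <- default_params$initial_angles
  q[1] <- hi[1] + 0.05
  fc <- joint_limit_forces(default_params, q, c(0, 0, 0))
  expect_lt(fc[1], 0)
  expect_identical(fc[2:3], c(0, 0))
  q2 <- q; q2[1] <- hi[1] + 0.10
  fc2 <- joint_limit_forces(default_params, q2, c(0, 0, 0))
  expect_lt(fc2[1], fc[1])  # deeper penetration, stronger restoring torque
})

test_that("moment arm matrix has one signed wrapping radius per muscle", {
  R <- moment_arm_matrix(default_params)
  expect_equal(dim(R), c(3, 6))
  expect_equal(R["shoulder", "shoulder_flexor"], 0.045)
  expect_equal(R["wrist", "wrist_extensor"], -0.035)
  expect_equal(colSums(R != 0), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(R[cbind(rep(1:3, each = 2), 1:6)] ==
                  rep(c(1, -1), 3) * rep(default_params$wrapping_radii,
                                         each = 2)))
})

test_that("muscle kinematics are optimal-length at the initial posture and linear", {
  spec <- muscle_spec()
  g0 <- muscle_lengths(default_params, spec, default_params$initial_angles,
                       c(0, 0, 0))
  expect_equal(g0$ltilde, rep(1, 6))
  expect_equal(g0$vtilde, rep(0, 6))
  dq <- 0.1
  q <- default_params$initial_angles + c(dq, 0, 0)
  g <- muscle_lengths(default_params, spec, q, c(0, 0, 0))
  expect_equal(g$l[1], spec$l0[1] - 0.045 * dq)  # flexor shortens
  expect_equal(g$l[2], spec$l0[2] + 0.045 * dq)  # extensor lengthens
  qd <- c(0.7, -0.3, 0.2)
  g1 <- muscle_lengths(default_params, spec, q, qd)
  g2 <- muscle_lengths(default_params, spec, q, 2 * qd)
  expect_equal(g2$vtilde, 2 * g1$vtilde)
  expect_gt(g1$vtilde[1], 0)  # flexion shortens the flexor
})

test_that("forward kinematics match geometry and the Jacobian oracle", {
  fk <- forward_kinematics(default_params, c(0, 0, 0))
  expect_equal(sqrt(sum(fk$x^2)), 0.32 + 0.25 + 0.18)
  expect_equal(fk$xdot, c(0, 0))
  set.seed(4)
  h <- 1e-7
  for (i in 1:10) {
    q <- random_q()
    J <- forward_kinematics(default_params, q)$J
    Jfd <- sapply(1:3, function(k) {
      dq <- numeric(3); dq[k] <- h
      (forward_kinematics(default_params, q + dq)$x -
       forward_kinematics(default_params, q - dq)$x) / (2 * h)
    })
    expect_equal(J, Jfd, tolerance = 1e-8)
    qd <- rnorm(3)
    expect_equal(forward_kinematics(default_params, q, qd)$xdot,
                 as.numeric(J %*% qd))
  }
})

test_that("dynamics rest at equilibrium and agree with M^-1 T on the first step", {
  st <- arm_state(default_params$initial_angles)
  st1 <- step_dynamics(default_params, st, c(0, 0, 0))
  expect_equal(st1$q, st$q)
  expect_equal(st1$qdot, c(0, 0, 0))
  torque <- c(0.5, 0, 0)
  st2 <- step_dynamics(default_params, st, torque)
  qacc <- solve(inertia_matrix(default_params, st$q), torque)
  expect_equal(st2$qdot, as.numeric(qacc * default_params$dt),
               tolerance = 1e-12)
})

test_that("passive motion conserves kinetic energy, improving with step refinement", {
  drift <- function(dt) {
    p <- arm_params(dt = dt)
    st <- arm_state(p$initial_angles, c(0.3, -0.2, 0.4))
    e0 <- 0.5 * sum(st$qdot * (inertia_matrix(p, st$q) %*% st$qdot))
    for (i in seq_len(round(1 / dt))) {
      st <- step_dynamics(p, st, c(0, 0, 0))
      expect_true(all(st$q >= p$joint_ranges[1, ] &
                      st$q <= p$joint_ranges[2, ]))
    }
    e1 <- 0.5 * sum(st$qdot * (inertia_matrix(p, st$q) %*% st$qdot))
    abs(e1 - e0) / e0
  }
  d2 <- drift(0.002)
  d1 <- drift(0.001)
  expect_lt(d2, 1e-2)
  expect_lt(d1, d2 / 2 * 1.1)  # at least first-order convergence
})

test_that("step_dynamics rejects non-finite states", {
  st <- arm_state(default_params$initial_angles)
  st$q[1] <- NaN
  expect_error(step_dynamics(default_params, st, c(0, 0, 0)), "blow-up")
})
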