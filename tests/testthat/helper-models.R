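# shared fixtures, built in code

default_params <- arm_params()

# random joint configuration strictly inside the feasible range
random_q <- function(margin = 0.05) {
  lo <- default_params$joint_ranges[1, ]
  hi <- default_params$joint_ranges[2, ]
  lo + (margin + (1 - 2 * margin) * runif(3)) * (hi - lo)
}

# independent kinetic-energy oracle: COM positions from explicit planar
# geometry, COM velocities by central-difference Jacobians, rod inertias
kinetic_energy_oracle <- function(q, qd) {
  L <- default_params$link_lengths[2:4]
  m <- default_params$link_masses[2:4]
  com <- function(q) {
    th <- cumsum(q)
    joints <- rbind(c(0, 0),
                    c(L[1] * cos(th[1]), L[1] * sin(th[1])))
    joints <- rbind(joints, joints[2, ] + c(L[2] * cos(th[2]),
                                            L[2] * sin(th[2])))
    t(sapply(1:3, function(i)
      joints[i, ] + 0.5 * c(L[i] * cos(th[i]), L[i] * sin(th[i]))))
  }
  h <- 1e-6
  ke <- 0
  for (i in 1:3) {
    v <- c(0, 0)
    for (k in 1:3) {
      dq <- numeric(3); dq[k] <- h
      v <- v + (com(q + dq)[i, ] - com(q - dq)[i, ]) / (2 * h) * qd[k]
    }
    omega <- sum(qd[1:i])
    ke <- ke + 0.5 * m[i] * sum(v^2) + 0.5 * (m[i] * L[i]^2 / 12) * omega^2
  }
  ke
}

# inertia matrix as the Hessian of the kinetic energy in the velocities
inertia_oracle <- function(q) {
  h <- 1e-3  # KE is exactly quadratic in qd, so h only sets rounding
  M <- matrix(0, 3, 3)
  for (k in 1:3) for (l in 1:3) {
    ek <- numeric(3); ek[k] <- h
    el <- numeric(3); el[l] <- h
    M[k, l] <- (kinetic_energy_oracle(q, ek + el) -
                kinetic_energy_oracle(q, ek - el) -
                kinetic_energy_oracle(q, el - ek) +
                kinetic_energy_oracle(q, -ek - el)) / (4 * h^2)
  }
  M
}

# Lagrangian oracle for the velocity-product torques:
# c_k = sum_l [dM/dt qd]_k - d/dq_k (0.5 qd' M qd), with M finite-differenced
bias_oracle <- function(q, qd) {
  h <- 1e-6
  dMdq <- lapply(1:3, function(k) {
    dq <- numeric(3); dq[k] <- h
    (inertia_matrix(default_params, q + dq) -
     inertia_matrix(default_params, q - dq)) / (2 * h)
  })
  Mdot <- Reduce(`+`, Map(function(D, v) D * v, dMdq, as.list(qd)))
  dKdq <- sapply(1:3, function(k)
    0.5 * as.numeric(qd %*% dMdq[[k]] %*% qd))
  as.numeric(Mdot %*% qd) - dKdq
}

# short, well-behaved tasks for quick closed-loop checks
short_targets <- function(x0, T_max = 0.6) make_targets(x0, T_max = T_max)

gentle_gains <- control_params(c(500, 150, 10), c(60, 15, 0.5), 0)
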