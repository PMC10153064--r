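test_that("muscle_spec defaults match the reference parameterisation", {
  s <- muscle_spec()
  expect_equal(s$f_max, c(1500, 1500, 1300, 1000, 500, 300))
  expect_equal(s$b, c(1.3, -1.3, 0.53))
  expect_equal(s$d, c(4, 1.8, 30.24))
  expect_equal(s$v_max, 1.6)
  expect_equal(s$alpha_O1, c(0.0945, 0.065))
  expect_equal(s$alpha_O3, c(0.018, 0.040, 0.025))
  expect_equal(s$beta_O3, c(0.6, 0.8, 0.7))
  expect_error(muscle_spec(beta_O3 = c(0.6, 0.8, 1.2)))
  expect_error(muscle_spec(f_max = rep(-1, 6)))
})

test_that("the five named variants combine activation and force models correctly", {
  expected <- list("FMAX" = c("IAM", "FMAX"), "FMAX+O1" = c("O1", "FMAX"),
                   "FLV+O1" = c("O1", "FLV"), "FMAX+O3" = c("O3", "FMAX"),
                   "FLV+O3" = c("O3", "FLV"))
  for (nm in muscle_variants()) {
    v <- muscle_variant(nm)
    expect_equal(c(v$activation_model, v$force_model), expected[[nm]])
  }
  expect_error(muscle_variant("FLV+O2"), "unknown")
})

test_that("force-length curve has its maximum at optimal length with known values", {
  expect_equal(fl_curve(1), 1)
  expect_equal(fl_curve(0.8), 0.5745844897, tolerance = 1e-9)
  # b2 < 0: the curve approaches exp(-(1/b3)^b1) for long muscles
  expect_equal(fl_curve(1e8), 0.1020124167, tolerance = 1e-6)
  expect_error(fl_curve(0), "ltilde > 0")
  lt <- seq(0.4, 2.5, by = 0.01)
  y <- fl_curve(lt)
  expect_true(all(y > 0 & y <= 1))
  expect_true(all(diff(y[lt < 1]) > 0))   # rising below optimal length
  expect_true(all(diff(y[lt > 1]) < 0))   # falling above
})

test_that("force-velocity curve is continuous, decreasing, with known values", {
  expect_equal(fv_curve(0), 1)
  expect_equal(fv_curve(1), 0)
  expect_equal(fv_curve(0.5), 1 / 6)
  expect_equal(fv_curve(-0.5), 1.7751861042, tolerance = 1e-9)
  v <- seq(-3, 1, by = 0.01)
  y <- fv_curve(v)
  expect_true(all(diff(y) < 0))
  expect_lt(max(y), 1.8 + 0.8 / 30.24)  # supremum d2 + (d2-1)/d3
  expect_equal(fv_curve(1.7), 0)        # clamped above v_max
})

test_that("force capacity reduces to isometric strengths where expected", {
  fmax <- muscle_spec()$f_max
  s_const <- muscle_variant("FMAX")
  s_flv <- muscle_variant("FLV+O3")
  expect_equal(force_capacity(s_const, runif(6, 0.5, 1.5), runif(6, -1, 1)),
               fmax)
  expect_equal(force_capacity(s_flv, rep(1, 6), rep(0, 6)), fmax)
  # monotone non-increasing in shortening velocity at fixed length
  vt <- seq(0, 1, by = 0.05)
  F <- sapply(vt, function(v) force_capacity(s_flv, rep(0.9, 6), rep(v, 6))[1])
  expect_true(all(diff(F) <= 0))
})

test_that("activation models track excitation as specified", {
  dt <- 0.002
  u <- rep(0.3, 6)
  st <- activation_step(muscle_variant("FMAX"), activation_state(), u, dt)
  expect_identical(st$a, u)  # instantaneous

  for (v in c("FMAX+O1", "FMAX+O3")) {
    st <- activation_state()
    spec <- muscle_variant(v)
    for (i in seq_len(1000))
      st <- activation_step(spec, st, rep(1, 6), dt)
    expect_equal(st$a, rep(1, 6), tolerance = 1e-3)  # steady state at u = 1
  }

  st <- activation_step(muscle_variant("FMAX+O3"), activation_state(),
                        rep(0, 6), dt)
  expect_identical(st$a, rep(0, 6))  # origin is a fixed point
  expect_identical(st$a1, rep(0, 6))

  expect_error(activation_step(muscle_spec(), activation_state(),
                               rep(1.5, 6), dt), "\\[0, 1\\]")
})

test_that("activation stays in [0,1] and O1 approaches a constant input monotonically", {
  set.seed(7)
  spec1 <- muscle_variant("FMAX+O1")
  spec3 <- muscle_variant("FMAX+O3")
  st1 <- activation_state(); st3 <- activation_state()
  for (i in 1:300) {
    u <- runif(6)
    st1 <- activation_step(spec1, st1, u, 0.002)
    st3 <- activation_step(spec3, st3, u, 0.002)
    for (st in list(st1, st3))
      expect_true(all(st$a >= 0 & st$a <= 1 & st$a1 >= 0 & st$a1 <= 1 &
                      st$a2 >= 0 & st$a2 <= 1))
  }
  st <- activation_state()
  prev <- 0
  for (i in 1:400) {
    st <- activation_step(spec1, st, rep(0.7, 6), 0.002)
    expect_gte(st$a[1], prev)
    expect_lte(st$a[1], 0.7 + 1e-12)
    prev <- st$a[1]
  }
})

test_that("O3 cascade states lead activation during the rising phase", {
  spec <- muscle_variant("FMAX+O3")
  st <- activation_state()
  for (i in 1:100) {  # constant step input, rising phase
    st <- activation_step(spec, st, rep(1, 6), 0.002)
    expect_true(all(st$a1 >= st$a2 - 1e-12 & st$a2 >= st$a - 1e-12))
  }
})

test_that("O3 cascade matches an adaptive ODE solver on the twitch protocol", {
  skip_if_not_installed("deSolve")
  al <- c(0.018, 0.040, 0.025); be <- c(0.6, 0.8, 0.7)
  rhs <- function(t, y, parms) {
    u <- if (t < 0.002) 1 else 0
    list(c((u - (be[1] + (1 - be[1]) * u) * y[1]) / al[1],
           (y[1] - (be[2] + (1 - be[2]) * y[1]) * y[2]) / al[2],
           (y[2] - (be[3] + (1 - be[3]) * y[2]) * y[3]) / al[3]))
  }
  times <- seq(0, 0.4, by = 1e-3)
  ode <- deSolve::ode(c(0, 0, 0), times, rhs, NULL, method = "ode45")
  tr <- twitch_response(muscle_variant("FMAX+O3"), dt = 5e-5, t_end = 0.4)
  ours <- tr$a[match(round(times, 6), round(tr$t, 6))]
  expect_lt(max(abs(ours - ode[, 4])), 0.005 * max(ode[, 4]))
})

test_that("twitch calibration reproduces the published characteristics", {
  tc <- twitch_characteristics(muscle_variant("FMAX+O3"))
  expect_equal(tc$time_to_peak, 0.070, tolerance = 0.02)
  expect_equal(tc$peak_amplitude, 0.0423, tolerance = 0.01)
  expect_equal(tc$half_relaxation_time, 0.082, tolerance = 0.02)

  # O1 time constants were chosen to match the O3 peak and half-relaxation
  t1 <- twitch_characteristics(muscle_variant("FMAX+O1"))
  expect_equal(t1$peak_amplitude, tc$peak_amplitude, tolerance = 0.05)
  expect_equal(t1$half_relaxation_time, tc$half_relaxation_time,
               tolerance = 0.05)

  ti <- twitch_characteristics(muscle_variant("FMAX"))
  expect_equal(ti$peak_amplitude, 1)
  expect_lte(ti$time_to_peak, 0.002)
})

test_that("twitch characteristics converge under step refinement", {
  a <- twitch_characteristics(muscle_variant("FMAX+O3"), dt = 1e-4, t_end = 1)
  b <- twitch_characteristics(muscle_variant("FMAX+O3"), dt = 5e-5, t_end = 1)
  expect_equal(a$time_to_peak, b$time_to_peak, tolerance = 5e-3)
  expect_equal(a$peak_amplitude, b$peak_amplitude, tolerance = 5e-3)
  expect_equal(a$half_relaxation_time, b$half_relaxation_time,
               tolerance = 5e-3)
})

test_that("twitch_table lines up the three activation models", {
  tt <- twitch_table(t_end = 0.3)
  expect_named(tt, c("t", "IAM", "O1", "O3"))
  expect_equal(max(tt$IAM), 1)
  expect_lt(max(tt$O3), max(tt$O1) * 1.05)
})
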