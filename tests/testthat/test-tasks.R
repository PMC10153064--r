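test_that("planned duration follows the cube-root scaling", {
  expect_equal(planned_duration(0.2175), 1.03, tolerance = 5e-3)
  expect_equal(planned_duration(1), 1.712)
  expect_equal(planned_duration(0.008), 0.3424)
  expect_error(planned_duration(0), "positive")
})

test_that("minimum-jerk profile is a normalised bell", {
  T_p <- 1.03
  expect_equal(min_jerk_speed(0, T_p), 0)
  expect_equal(min_jerk_speed(T_p, T_p), 0)
  expect_equal(min_jerk_speed(T_p / 2, T_p), 1.875 / T_p)
  expect_gte(min(min_jerk_speed(seq(0, 2, by = 0.01), T_p)), 0)
  expect_equal(stats::integrate(min_jerk_speed, 0, T_p, T_p = T_p)$value, 1,
               tolerance = 1e-8)
})

test_that("the four targets surround the initial endpoint symmetrically", {
  x0 <- c(0.1673, 0.5115)
  tg <- make_targets(x0)
  expect_named(tg, c("right", "forward", "left", "back"))
  for (t in tg) expect_equal(t$d0, 0.2175)
  expect_equal(tg$forward$x_t + tg$back$x_t, 2 * x0)
  expect_equal(tg$right$x_t + tg$left$x_t, 2 * x0)
  expect_equal(length(unique(lapply(tg, `[[`, "x_t"))), 4)
  expect_equal(tg$right$T_max, 4)
  expect_equal(tg$right$eps_tol, 1e-3)
  expect_equal(tg$right$T_p, planned_duration(0.2175))
})

test_that("the plan starts at rest, ends on the target, and moves at the profile speed", {
  task <- reach_task(c(0.3, 0.6), c(0.1, 0.5))
  plan <- trajectory_plan(task)
  expect_equal(plan_position(plan, 0), task$x0)
  expect_equal(plan_position(plan, task$T_p), task$x_t)
  expect_equal(plan_position(plan, task$T_p + 2), task$x_t)
  expect_equal(plan_velocity(plan, task$T_p + 0.1), c(0, 0))
  ts <- seq(0.05, task$T_p - 0.05, by = 0.05)
  for (t in ts)
    expect_equal(sqrt(sum(plan_velocity(plan, t)^2)),
                 task$d0 * min_jerk_speed(t, task$T_p))
})

test_that("movement error measures the time-averaged deviation", {
  task <- reach_task(c(0.3, 0.6), c(0.1, 0.5), T_max = 2)
  plan <- trajectory_plan(task)
  t <- seq(0, task$T_max, by = 0.002)
  xd <- t(vapply(t, function(ti) plan_position(plan, ti), numeric(2)))
  expect_equal(movement_error(t, xd, plan), 0)
  offset <- c(3e-3, -4e-3)  # norm 5 mm
  x <- sweep(xd, 2, offset, "+")
  expect_equal(movement_error(t, x, plan), 5e-3)
  x2 <- sweep(xd, 2, offset / 2, "+")
  expect_equal(movement_error(t, x2, plan), 2.5e-3)
  expect_error(movement_error(t[-1], x, plan), "mismatch")
})

test_that("stabilisation error starts at first success and falls back to e_mv on failure", {
  task <- reach_task(c(0.3, 0.6), c(0.1, 0.5), T_max = 2)
  plan <- trajectory_plan(task)
  t <- seq(0, task$T_max, by = 0.002)
  xd <- t(vapply(t, function(ti) plan_position(plan, ti), numeric(2)))

  st <- stabilisation_error(t, xd, plan)
  expect_equal(st$e_st, 0)
  expect_equal(st$t_succ, t[t >= task$T_p][1])

  # never within tolerance: t_succ = 0 and e_st = e_mv
  x_off <- sweep(xd, 2, c(5e-3, 0), "+")
  st2 <- stabilisation_error(t, x_off, plan, eps_tol = 1e-3)
  expect_equal(st2$t_succ, 0)
  expect_equal(st2$e_st, movement_error(t, x_off, plan))

  # deviation only before success leaves e_st at zero while e_mv > 0
  x_mix <- xd
  early <- t < task$T_p
  x_mix[early, ] <- x_mix[early, ] + 0.01
  st3 <- stabilisation_error(t, x_mix, plan)
  expect_equal(st3$e_st, 0)
  expect_gt(movement_error(t, x_mix, plan), 0)
})

test_that("co-contraction is the overlap of opposing muscle forces", {
  t <- seq(0, 1, by = 0.01)
  n <- length(t)
  forces <- matrix(0, n, 6)
  forces[, 1] <- 100  # shoulder flexor only: no overlap
  cc <- co_contraction(t, forces)
  expect_equal(cc$average, c(shoulder = 0, elbow = 0, wrist = 0))

  forces[, 2] <- 30   # extensor at 30 N: overlap is the minimum
  forces[, 3] <- 50; forces[, 4] <- 80
  cc <- co_contraction(t, forces)
  expect_equal(unname(cc$average), c(30, 50, 0))
  expect_equal(unname(cc$percent),
               c(30 / 1500, 50 / 1000, 0) * 100)
  cc_mean <- co_contraction(t, forces, normalise = "mean")
  expect_equal(unname(cc_mean$percent[1]), 30 / 1500 * 100)
  expect_equal(unname(cc_mean$percent[2]), 50 / 1150 * 100)
})

test_that("metrics are invariant under rigid translation of the scene", {
  task <- reach_task(c(0.3, 0.6), c(0.1, 0.5), T_max = 2)
  plan <- trajectory_plan(task)
  t <- seq(0, task$T_max, by = 0.002)
  set.seed(17)
  xd <- t(vapply(t, function(ti) plan_position(plan, ti), numeric(2)))
  x <- xd + matrix(rnorm(2 * length(t), sd = 5e-4), ncol = 2)

  shift <- c(1.3, -0.7)
  task2 <- reach_task(task$x_t + shift, task$x0 + shift, T_max = 2)
  plan2 <- trajectory_plan(task2)
  x2 <- sweep(x, 2, shift, "+")
  expect_equal(movement_error(t, x, plan), movement_error(t, x2, plan2))
  expect_equal(stabilisation_error(t, x, plan),
               stabilisation_error(t, x2, plan2))
})
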