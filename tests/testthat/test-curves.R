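test_that("interpolation fills probe gaps linearly and refuses extrapolation", {
  cv <- learning_curve(c(1, 3), c(0, 1))
  expect_equal(interpolate_curve(cv, 2)$value, 0.5)
  expect_equal(interpolate_curve(cv, c(1, 3))$value, c(0, 1))  # identity
  expect_error(interpolate_curve(cv, 0:3), "beyond the curve span")
})

test_that("probe-sampled model curves re-interpolate close to the dense curve", {
  p <- default_two_state_params()
  sched <- build_schedule(standard_groups()$full112, seed = 2,
                          include_baseline = FALSE)
  traj <- simulate_two_state(p, sched)
  dense <- trajectory_curve(traj, observe = "all")
  probes <- trajectory_curve(traj, observe = "probes")
  grid <- seq(ceiling(min(probes$trial)), floor(max(probes$trial)))
  redone <- interpolate_curve(probes, grid)
  truth <- interpolate_curve(dense, grid)
  # bounded by local curvature: the curve bends fastest at the task switch
  expect_lt(max(abs(redone$value - truth$value)), 0.3)
  expect_lt(mean(abs(redone$value - truth$value)), 0.05)
})

test_that("moving average matches a brute-force windowed mean", {
  expect_equal(moving_average(learning_curve(1:3, c(0, 3, 0)))$value[2], 1)
  const <- learning_curve(1:10, rep(0.4, 10))
  expect_equal(moving_average(const)$value, rep(0.4, 10))
  set.seed(5)
  v <- rnorm(30)
  sm <- moving_average(learning_curve(1:30, v), window = 5)
  brute <- sapply(1:30, function(i) mean(v[max(1, i - 2):min(30, i + 2)]))
  expect_equal(sm$value, brute)
  expect_error(moving_average(const, window = 4), "odd")
})

test_that("zero-crossing location is linearly interpolated", {
  cv <- learning_curve(1:2, c(0.5, -0.5))
  expect_equal(find_zero_crossing(cv), 1.5)
  # down, up, down: the last-crossing rule takes the third crossing
  cv3 <- learning_curve(1:6, c(1, -0.2, 0.3, 0.4, -0.4, -1))
  z_last <- find_zero_crossing(cv3, "last")
  expect_gt(z_last, 4); expect_lt(z_last, 5)
  z_avg <- find_zero_crossing(cv3, "first_last_average")
  expect_equal(z_avg, (find_zero_crossing(learning_curve(1:2, c(1, -0.2))) +
                         z_last) / 2)
  # monotone curve: both rules agree
  mono <- learning_curve(1:5, c(2, 1, -1, -2, -3))
  expect_equal(find_zero_crossing(mono, "last"),
               find_zero_crossing(mono, "first_last_average"))
  expect_error(find_zero_crossing(learning_curve(1:4, c(1, 2, 3, 4))),
               "no positive-to-negative")
})

test_that("rectification flips and re-origins the opposite curve", {
  cv <- learning_curve(0:5, c(1, 0.5, -0.5, -1, -1.5, -2))
  z <- find_zero_crossing(cv)
  rect <- rectify_opposite(cv, z)
  expect_equal(min(rect$trial), 0)
  expect_equal(rect$value[1], 0)                 # value at the crossing
  # one trial past the crossing interpolates halfway between -(-0.5) and -(-1)
  expect_equal(interpolate_curve(rect, 1)$value, 0.75)
  expect_error(rectify_opposite(cv, 99), "outside")
})

test_that("interference metric anchors: equal curves -> 0, no learning -> 1", {
  init <- trajectory_curve(
    simulate_two_state(default_two_state_params(), ab_schedule(60, 0)))
  same <- ai_metric(init, init, window = 25)
  expect_equal(same$ai, 0)
  flat <- learning_curve(0:30, rep(0, 31))
  expect_equal(ai_metric(init, flat, window = 25)$ai, 1)
  expect_error(ai_metric(flat, init, window = 25), "not positive")
  # exact identity ai = 1 - mean_opposite / mean_initial
  half <- learning_curve(init$trial, init$value / 3)
  m <- ai_metric(init, half, window = 25)
  expect_identical(m$ai, 1 - m$mean_opposite / m$mean_initial)
})

test_that("window-mean and area-under-curve versions of the metric coincide", {
  p <- default_two_state_params()
  init <- trajectory_curve(simulate_two_state(p, ab_schedule(60, 0)))
  traj <- simulate_two_state(p, ab_schedule(112, 113))
  curve <- trajectory_curve(traj)
  z <- find_zero_crossing(curve, from = 112)
  rect <- rectify_opposite(curve, z)
  m_mean <- ai_metric(init, rect, window = 25, method = "mean")
  m_area <- ai_metric(init, rect, window = 25, method = "area")
  expect_lt(abs(m_mean$ai - m_area$ai), 1e-12)
})

test_that("the rectified opposite curve of a long AB run lies below initial learning", {
  p <- default_two_state_params()
  init <- trajectory_curve(simulate_two_state(p, ab_schedule(60, 0)))
  curve <- trajectory_curve(simulate_two_state(p, ab_schedule(369, 120)))
  rect <- rectify_opposite(curve, find_zero_crossing(curve, from = 369))
  gi <- interpolate_curve(init, 1:25)$value
  go <- interpolate_curve(rect, 1:25)$value
  expect_true(all(go < gi))
})

test_that("final learning averages the last 30% of Task A", {
  const <- learning_curve(1:13, rep(0.6, 13))
  expect_equal(final_learning(const, 13), 0.6)
  # the 13-trial group's window is trials 9-13
  ramp13 <- learning_curve(1:13, 1:13)
  expect_equal(final_learning(ramp13, 13), mean(9:13))
  # linear ramp oracle
  ramp <- learning_curve(1:100, (1:100) / 100)
  expect_equal(final_learning(ramp, 100), mean(70:100) / 100)
  expect_error(final_learning(learning_curve(1:5, 1:5), 100), "window")
})

test_that("onset-aligned metrics read the curve at and after Task B onset", {
  flat <- learning_curve(0:100, rep(0.3, 101))
  m <- onset_aligned_metrics(flat, k = 50, onset = 40)
  expect_equal(unname(m["adaptation_change"]), 0)
  lin <- learning_curve(0:100, 0.01 * (0:100))
  m2 <- onset_aligned_metrics(lin, k = 50, onset = 40)
  expect_equal(unname(m2["adaptation_change"]), 0.5)
  expect_equal(unname(m2["adaptation_at_k"]), 0.9)
  # model curve: interpolated values match a direct trajectory lookup
  p <- default_two_state_params()
  curve <- trajectory_curve(simulate_two_state(p, ab_schedule(369, 120)))
  m3 <- onset_aligned_metrics(curve, k = 50, onset = 369)
  expect_equal(unname(m3["adaptation_at_k"]),
               curve$value[curve$trial == 419])
  expect_error(onset_aligned_metrics(flat, k = 80, onset = 40), "shorter")
})

test_that("time-constant fits recover exponentials and order the groups", {
  t <- 0:60
  exact <- learning_curve(t, 0.8 * (1 - exp(-t / 10)))
  fit <- fit_time_constant(exact)
  expect_equal(fit$tau, 10, tolerance = 1e-6)
  expect_equal(fit$asymptote, 0.8, tolerance = 1e-6)
  # tau is invariant to amplitude
  scaled <- learning_curve(t, 0.25 * (1 - exp(-t / 10)))
  expect_equal(fit_time_constant(scaled)$tau, 10, tolerance = 1e-6)
  # opposite learning slows with Task A duration
  p <- default_two_state_params()
  tau_of <- function(nA) {
    curve <- trajectory_curve(simulate_two_state(p, ab_schedule(nA, 115)))
    rect <- rectify_opposite(curve, find_zero_crossing(curve, from = nA))
    fit_time_constant(interpolate_curve(rect, 0:floor(max(rect$trial))))$tau
  }
  expect_gt(tau_of(369), tau_of(13))
})

test_that("coefficient of variation is sd over mean and scale-invariant", {
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  expect_equal(coefficient_of_variation(rep(4, 6)), 0)
  set.seed(2); v <- runif(20, 1, 2)
  expect_equal(coefficient_of_variation(7 * v), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
})

test_that("curve aggregation averages pointwise over covering curves", {
  c1 <- learning_curve(0:10, rep(1, 11))
  c2 <- learning_curve(0:5, rep(0, 6))
  agg <- aggregate_curves(list(c1, c2), 0:10)
  expect_equal(agg$value[1:6], rep(0.5, 6))
  expect_equal(agg$value[7:11], rep(1, 5))   # only c1 covers 6..10
})
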