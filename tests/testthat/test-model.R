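test_that("a single update from rest learns one step of the error", {
  p <- toy_params()
  s <- step_two_state(0, 0, p, disturbance = 1, kind = "field")
  expect_equal(s$error, 1)
  expect_equal(s$x_fast, p$fast$learning_rate)
  expect_equal(s$x_slow, p$slow$learning_rate)
})

test_that("field-trial update matches hand arithmetic", {
  p <- two_state_params(process_params(0.9, 0.1), process_params(0.99, 0.01))
  s <- step_two_state(0.2, 0.1, p, disturbance = 1, kind = "field")
  expect_equal(s$error, 0.7)
  expect_equal(s$x_fast, 0.9 * 0.2 + 0.1 * 0.7)   # 0.25
  expect_equal(s$x_slow, 0.99 * 0.1 + 0.01 * 0.7) # 0.106
})

test_that("clamp trials decay the states without error", {
  p <- toy_params()
  s <- step_two_state(0.4, -0.2, p, disturbance = 1, kind = "clamp")
  expect_equal(s$error, 0)
  expect_equal(s$x_fast, 0.9 * 0.4)
  expect_equal(s$x_slow, 0.99 * -0.2)
})

test_that("null trials drive unlearning through the absent disturbance", {
  p <- toy_params()
  s <- step_two_state(0.4, 0.2, p, disturbance = 1, kind = "null")
  expect_equal(s$error, -0.6)
})

test_that("non-finite inputs are rejected with a diagnostic", {
  p <- toy_params()
  expect_error(step_two_state(NaN, 0, p, 1, "field"), "non-finite")
  expect_error(step_two_state(0, 0, p, Inf, "field"), "non-finite")
})

test_that("zero disturbance from rest stays identically at rest", {
  sched <- disturbance_schedule(rep(0, 50), rep("field", 50),
                                rep("taskA", 50))
  traj <- simulate_two_state(toy_params(), sched)
  expect_true(all(traj$x_net == 0))
  traj1 <- simulate_single_process(process_params(0.9923, 0.03), sched)
  expect_true(all(traj1$x_net == 0))
})

test_that("long constant-disturbance runs converge to the closed-form fixed point", {
  for (p in list(toy_params(), default_two_state_params())) {
    for (f in c(1, -1, 0.5)) {
      traj <- simulate_two_state(p, ab_schedule(10000, 0, strength_a = f))
      ss <- steady_state(p, f)
      expect_equal(tail(traj$x_net, 1), unname(ss["x_net"]), tolerance = 1e-9)
      expect_equal(tail(traj$x_fast, 1), unname(ss["x_fast"]), tolerance = 1e-9)
    }
  }
  # single process: f * B / (1 - A + B)
  sp <- process_params(0.9923, 0.03)
  traj <- simulate_single_process(sp, ab_schedule(20000, 0))
  expect_equal(tail(traj$x_net, 1), 0.03 / (1 - 0.9923 + 0.03),
               tolerance = 1e-9)
})

test_that("symmetric steady-state algebra gives 2/3", {
  # g_fast = g_slow = 1
  p <- two_state_params(process_params(0.9, 0.1), process_params(0.95, 0.05))
  expect_equal(unname(steady_state(p, 1)["x_net"]), 2 / 3)
  expect_equal(steady_state(p, 0), c(x_fast = 0, x_slow = 0, x_net = 0))
})

test_that("retention of 1 with a nonzero learning rate has no fixed point", {
  p <- two_state_params(process_params(0.9, 0.1), process_params(1, 0.01))
  expect_error(steady_state(p, 1), "no fixed point")
})

test_that("the slow process is still biased toward Task A at the zero-crossing", {
  traj <- simulate_two_state(default_two_state_params(), ab_schedule(369, 120))
  xb <- traj[traj$phase == "taskB", ]
  cross <- which(xb$x_net <= 0)[1]
  expect_false(is.na(cross))
  expect_gt(xb$x_slow[cross], 0)
  expect_lt(xb$x_fast[cross], 0)
})

test_that("divergent trajectories abort naming the trial", {
  sched <- ab_schedule(50, 0)
  expect_error(simulate_two_state(toy_params(), sched, bound = 1e-3),
               "diverged at trial 1")
})

test_that("the model is linear: scaling and superposition", {
  p <- default_two_state_params()
  set.seed(7)
  for (rep in 1:3) {
    d1 <- rnorm(80); d2 <- rnorm(80)
    mk <- function(d) disturbance_schedule(d, rep("field", 80),
                                           rep("taskA", 80))
    x1 <- simulate_two_state(p, mk(d1))$x_net
    x2 <- simulate_two_state(p, mk(d2))$x_net
    xs <- simulate_two_state(p, mk(d1 + d2))$x_net
    xc <- simulate_two_state(p, mk(2.5 * d1))$x_net
    expect_equal(xs, x1 + x2, tolerance = 1e-12)
    expect_equal(xc, 2.5 * x1, tolerance = 1e-12)
  }
})

test_that("clamp trials never increase the state magnitudes", {
  p <- default_two_state_params()
  sched <- build_schedule(standard_groups()$full41, seed = 3)
  traj <- simulate_two_state(p, sched)
  after <- c(traj$x_fast[-1], attr(traj, "x_fast_end"))
  after_s <- c(traj$x_slow[-1], attr(traj, "x_slow_end"))
  cl <- traj$kind == "clamp"
  expect_true(all(abs(after[cl]) <= abs(traj$x_fast[cl]) + 1e-15))
  expect_true(all(abs(after_s[cl]) <= abs(traj$x_slow[cl]) + 1e-15))
})

test_that("clamp_mode = 'skip' leaves the states untouched on clamp trials", {
  p <- toy_params()
  sched <- disturbance_schedule(c(1, 1, 1), c("field", "clamp", "field"),
                                rep("taskA", 3))
  traj <- simulate_two_state(p, sched, clamp_mode = "skip")
  expect_equal(traj$x_fast[3], traj$x_fast[2])
  expect_equal(traj$x_slow[3], traj$x_slow[2])
})

test_that("trajectory CSV round-trips the state columns", {
  traj <- simulate_two_state(toy_params(), ab_schedule(20, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- utils::read.csv(path)
  expect_equal(back$x_net, traj$x_net, tolerance = 1e-12)
})
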