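test_that("minimum-jerk profile conserves displacement and peaks at 1.875 L/T", {
  vel <- minimum_jerk_velocity(length = 0.1, duration = 0.5, sample_rate = 200)
  dt <- vel$time[2] - vel$time[1]
  # trapezoidal displacement
  disp <- sum((vel$velocity[-1] + vel$velocity[-nrow(vel)]) / 2) * dt
  expect_equal(disp, 0.1, tolerance = 1e-6)
  expect_equal(max(vel$velocity), 1.875 * 0.1 / 0.5, tolerance = 1e-9)
  # peak at the window midpoint, profile symmetric about it
  mid <- (nrow(vel) + 1L) %/% 2L
  expect_equal(which.max(vel$velocity), mid)
  expect_equal(vel$velocity, rev(vel$velocity), tolerance = 1e-12)
  expect_equal(vel$time[nrow(vel)] - vel$time[1], 2.25)
})

test_that("ideal force is the gain-scaled velocity with linear gain", {
  mj <- mj_ideal_pair()
  expect_equal(max(mj$full$force), 15 * 0.375, tolerance = 1e-9)  # 5.625 N
  expect_equal(mj$half$force, 0.5 * mj$full$force)
  expect_equal(ideal_force(data.frame(time = 1:5, velocity = rep(0, 5)),
                           15)$force, rep(0, 5))
  expect_error(ideal_force(mj$vel, -1), "positive")
})

test_that("baseline subtraction removes a known offset exactly", {
  mj <- mj_ideal_pair()
  base <- lapply(1:5, function(i)
    force_trace(mj$vel$time, rep(0.8, nrow(mj$vel)), mj$vel$velocity,
                phase = "baseline"))
  bl <- baseline_average(base)
  expect_equal(bl$lateral_force, base[[1]]$lateral_force)
  tr <- force_trace(mj$vel$time, mj$full$force + 0.8, mj$vel$velocity)
  expect_equal(baseline_subtract(tr, bl)$lateral_force, mj$full$force)
  # trace minus itself is the zero trace
  expect_equal(baseline_subtract(tr, tr)$lateral_force,
               rep(0, nrow(mj$vel)))
  expect_error(baseline_average(base[1:3]), "at least 5")
})

test_that("adaptation index anchors: ideal -> 1, zero -> 0, half -> 0.5", {
  mj <- mj_ideal_pair()
  mk <- function(f) force_trace(mj$vel$time, f, mj$vel$velocity)
  expect_equal(adaptation_index(mk(mj$full$force), mj$full)$adaptation_index, 1)
  expect_equal(adaptation_index(mk(rep(0, nrow(mj$vel))),
                                mj$full)$adaptation_index, 0)
  expect_equal(adaptation_index(mk(mj$half$force), mj$full)$adaptation_index,
               0.5)
})

test_that("the default index ignores orthogonal components bit-for-bit", {
  mj <- mj_ideal_pair()
  x <- mj$full$force
  set.seed(11)
  for (k in 1:5) {
    raw <- rnorm(length(x))
    ortho <- raw - sum(raw * x) / sum(x * x) * x   # zero inner product
    m0 <- adaptation_index(0.7 * x, mj$full)$adaptation_index
    m1 <- adaptation_index(0.7 * x + ortho, mj$full)$adaptation_index
    expect_lt(abs(m1 - m0), 1e-10)
    expect_equal(m0, 0.7, tolerance = 1e-12)
  }
})

test_that("all four estimators agree exactly on noise-free scaled traces", {
  mj <- mj_ideal_pair()
  for (c0 in c(0.3, 1, -0.4)) {
    for (method in c("ols_yx", "ols_xy_inverse", "deming", "pca")) {
      m <- adaptation_index(c0 * mj$full$force, mj$full, method = method)
      expect_equal(m$adaptation_index, c0, tolerance = 1e-9,
                   info = paste(method, c0))
    }
  }
})

test_that("the default index is scale-equivariant and its R^2 lies in [0, 1]", {
  mj <- mj_ideal_pair()
  set.seed(3)
  y <- 0.6 * mj$full$force + rnorm(nrow(mj$vel), 0, 0.3)
  m1 <- adaptation_index(y, mj$full)
  m2 <- adaptation_index(2 * y, mj$full)
  expect_equal(m2$adaptation_index, 2 * m1$adaptation_index)
  expect_gte(m1$r_squared, 0); expect_lte(m1$r_squared, 1)
})

test_that("the inverse-regression estimator flags near-zero denominators", {
  mj <- mj_ideal_pair()
  set.seed(4)
  noise_only <- rnorm(nrow(mj$vel), 0, 0.5)
  m <- adaptation_index(noise_only, mj$full, method = "ols_xy_inverse")
  expect_true(m$unstable)
  expect_error(adaptation_index(mj$full$force,
                                ideal_force(data.frame(time = mj$vel$time,
                                                       velocity = 0), 15)),
               "zero variance")
})

test_that("mid-movement force averages the 250 ms window around peak speed", {
  mj <- mj_ideal_pair()
  const <- force_trace(mj$vel$time, rep(2.5, nrow(mj$vel)), mj$vel$velocity)
  expect_equal(mid_movement_force(const), 2.5)
  zero <- force_trace(mj$vel$time, rep(0, nrow(mj$vel)), mj$vel$velocity)
  expect_equal(mid_movement_force(zero), 0)
  # direct re-summation oracle on the ideal trace
  tr <- force_trace(mj$vel$time, mj$full$force, mj$vel$velocity)
  mid <- which.max(mj$vel$velocity)
  idx <- (mid - 25):(mid + 25)            # 125 ms at 200 Hz
  expect_equal(mid_movement_force(tr), mean(mj$full$force[idx]))
  # linear in the trace
  tr2 <- force_trace(mj$vel$time, 2 * mj$full$force + 1, mj$vel$velocity)
  expect_equal(mid_movement_force(tr2), 2 * mid_movement_force(tr) + 1)
})

test_that("orientation standardizes subject direction and task phase", {
  v <- c(0.2, -0.5)
  expect_equal(orient(v, "CW", "taskA"), v)
  expect_equal(orient(v, "CCW", "taskA"), -v)
  # a subject fully adapted to Task B reads -1 on the Task A convention:
  # its slope against the Task B ideal is +1, negated once
  expect_equal(orient(1, "CW", "taskB"), -1)
  expect_equal(orient(1, "CCW", "taskB"), 1)
  expect_error(orient(v, "up", "taskA"), "field_direction")
  expect_error(orient(v, "CW", "washout"), "phase")
})

test_that("force traces survive a long-format CSV round-trip", {
  mj <- mj_ideal_pair()
  traces <- list(
    force_trace(mj$vel$time, mj$full$force, mj$vel$velocity,
                subject = "s1", trial = 4L, phase = "taskA",
                field_direction = "CW"),
    force_trace(mj$vel$time, mj$half$force, mj$vel$velocity,
                subject = "s1", trial = 9L, phase = "taskB",
                field_direction = "CW"))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_traces_csv(traces, path)
  back <- read_traces_csv(path)
  expect_length(back, 2L)
  got <- back[[which(vapply(back, `[[`, 0L, "trial") == 4L)]]
  expect_equal(got$lateral_force, traces[[1]]$lateral_force,
               tolerance = 1e-9)
})

test_that("trace validation enforces the alignment contract", {
  mj <- mj_ideal_pair()
  expect_error(force_trace(mj$vel$time[1:100], mj$full$force[1:100],
                           mj$vel$velocity[1:100]), "2.25")
  shifted <- c(mj$vel$velocity[-1], 0)
  expect_error(force_trace(mj$vel$time, mj$full$force, shifted), "midpoint")
})
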