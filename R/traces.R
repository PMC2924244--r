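#' Minimum-jerk velocity profile in a probe-trial window
#'
#' Closed-form minimum-jerk speed profile for a point-to-point reach of
#' length `L` and duration `T`, embedded in a zero-padded window of
#' `span` seconds centered on the peak-speed sample. The peak speed of a
#' minimum-jerk reach is `1.875 * L / T` (0.375 m/s for the 10 cm,
#' 500 ms reaches used throughout).
#'
#' @param length Reach length in meters (default 0.1).
#' @param duration Reach duration in seconds (default 0.5).
#' @param sample_rate Sampling rate in Hz (default 200).
#' @param span Window span in seconds (default 2.25).
#' @return A data frame with columns `time` (seconds, 0 at window start)
#'   and `velocity` (m/s).
#' @export
minimum_jerk_velocity <- function(length = 0.1, duration = 0.5,
                                  sample_rate = 200, span = 2.25) {
  if (length <= 0 || duration <= 0 || sample_rate <= 0 || span <= 0)
    stop("all arguments must be positive")
  if (duration > span) stop("movement duration exceeds the window span")
  dt <- 1 / sample_rate
  n <- round(span / dt) + 1L              # (n - 1) * dt == span
  time <- (seq_len(n) - 1L) * dt
  mid <- (n + 1L) %/% 2L                  # peak-speed sample at the midpoint
  t0 <- time[mid] - duration / 2          # movement start
  tau <- (time - t0) / duration
  v <- ifelse(tau >= 0 & tau <= 1,
              length / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4), 0)
  data.frame(time = time, velocity = v)
}

#' Ideal compensatory lateral force
#'
#' The viscous field pushes the hand laterally with a force proportional
#' to the longitudinal reach speed; the force that exactly counteracts
#' it is `field_gain` times the velocity profile, oriented against the
#' robot force. The returned trace uses the convention that positive
#' force is the compensation for the reference (clockwise, Task A)
#' field; negate it for the opposite field.
#'
#' @param velocity Data frame with `time` and `velocity` columns (see
#'   [minimum_jerk_velocity()]) or a numeric velocity vector.
#' @param field_gain Field strength in N s/m (15 full, 7.5 half).
#' @return A data frame of class `ideal_force` with columns `time` and
#'   `force` (newtons).
#' @export
ideal_force <- function(velocity, field_gain) {
  if (field_gain <= 0) stop("`field_gain` must be positive")
  if (is.numeric(velocity))
    velocity <- data.frame(time = seq_along(velocity) - 1, velocity = velocity)
  structure(data.frame(time = velocity$time,
                       force = field_gain * velocity$velocity),
            class = c("ideal_force", "data.frame"), field_gain = field_gain)
}

#' Lateral force trace from one error-clamp trial
#'
#' @param time Uniformly sampled time stamps spanning 2.25 s, with the
#'   peak longitudinal speed at the midpoint sample.
#' @param lateral_force Lateral force in newtons.
#' @param longitudinal_velocity Longitudinal speed in m/s.
#' @param subject,trial,phase,field_direction Metadata (direction is
#'   `"CW"` or `"CCW"`).
#' @param check Validate the alignment contract (default `TRUE`); set
#'   `FALSE` for noisy empirical traces whose peak is located later.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(time, lateral_force, longitudinal_velocity,
                        subject = NA_character_, trial = NA_integer_,
                        phase = NA_character_, field_direction = NA_character_,
                        check = TRUE) {
  n <- length(time)
  if (length(lateral_force) != n || length(longitudinal_velocity) != n)
    stop("trace components must have equal length")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("time must be uniformly sampled")
  if (check) {
    if (abs((time[n] - time[1]) - 2.25) > dt[1] + 1e-9)
      stop("trace span must be 2.25 s (got ", time[n] - time[1], ")")
    mid <- (n + 1L) %/% 2L
    if (which.max(longitudinal_velocity) != mid)
      stop("peak longitudinal speed must lie at the trace midpoint")
  }
  structure(list(time = time, lateral_force = lateral_force,
                 longitudinal_velocity = longitudinal_velocity,
                 subject = subject, trial = trial, phase = phase,
                 field_direction = field_direction),
            class = "force_trace")
}

#' Baseline force pattern and baseline subtraction
#'
#' The baseline is the mean force pattern over the last `n_baseline`
#' error-clamp trials before Task A onset; subtracting it removes
#' posture- and hardware-related force biases so the remaining force
#' reflects learned compensation.
#'
#' @param traces List of `force_trace` objects from pre-Task-A clamp
#'   trials.
#' @param n_baseline Number of trailing clamp trials to average
#'   (default 5).
#' @return `baseline_average()` returns a `force_trace`;
#'   `baseline_subtract()` the corrected `force_trace`.
#' @export
baseline_average <- function(traces, n_baseline = 5L) {
  if (length(traces) < n_baseline)
    stop("need at least ", n_baseline, " pre-Task-A clamp trials, have ",
         length(traces))
  use <- traces[seq(length(traces) - n_baseline + 1L, length(traces))]
  f <- rowMeans(vapply(use, `[[`, use[[1]]$lateral_force, "lateral_force"))
  v <- rowMeans(vapply(use, `[[`, use[[1]]$longitudinal_velocity,
                       "longitudinal_velocity"))
  force_trace(use[[1]]$time, f, v, subject = use[[1]]$subject,
              phase = "baseline", check = FALSE)
}

#' @rdname baseline_average
#' @param trace A `force_trace`.
#' @param baseline The baseline `force_trace`.
#' @export
baseline_subtract <- function(trace, baseline) {
  if (length(trace$time) != length(baseline$time) ||
      any(abs(trace$time - baseline$time) > 1e-9))
    stop("trace and baseline time bases are not aligned")
  trace$lateral_force <- trace$lateral_force - baseline$lateral_force
  trace
}

#' Adaptation index of a force trace
#'
#' Regresses the produced lateral force pattern onto the ideal
#' compensatory pattern; the slope is the adaptation index (0 = no
#' learning, 1 = the aligned component equals the ideal). The default
#' estimator is ordinary least squares of actual on ideal through the
#' origin, which makes the slope exactly the size of the
#' ideal-aligned component and independent of any orthogonal component.
#' Alternative slope estimators: the reciprocal of the ideal-on-actual
#' OLS slope (`ols_xy_inverse`, flagged unstable when the actual trace
#' is near zero), orthogonal (Deming with error-variance ratio 1)
#' regression, and the ratio of leading principal-component loadings.
#'
#' @param actual A `force_trace` (baseline-subtracted).
#' @param ideal An [ideal_force()] trace of the same length.
#' @param method Estimator; see Details.
#' @param intercept Include an intercept in the OLS estimators
#'   (default `FALSE`; see the package vignette).
#' @return An object of class `adaptation_measure`: list with
#'   `adaptation_index`, `r_squared` (uncentered R^2 of the default
#'   estimator, `NA` otherwise), `method`, `unstable` flag.
#' @export
adaptation_index <- function(actual, ideal,
                             method = c("ols_yx", "ols_xy_inverse",
                                        "deming", "pca"),
                             intercept = FALSE) {
  method <- match.arg(method)
  y <- if (inherits(actual, "force_trace")) actual$lateral_force else actual
  x <- if (inherits(ideal, "ideal_force")) ideal$force else ideal
  if (length(x) != length(y)) stop("trace lengths differ")
  if (all(x == 0) || stats::var(x) == 0)
    stop("ideal force has zero variance; slope undefined")
  unstable <- FALSE
  r2 <- NA_real_
  if (method == "ols_yx") {
    if (intercept) {
      fit <- stats::lm.fit(cbind(1, x), y)
      slope <- fit$coefficients[2]
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    } else {
      slope <- sum(x * y) / sum(x * x)
      r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
      r2 <- max(0, min(1, r2))
    }
  } else if (method == "ols_xy_inverse") {
    denom <- if (intercept) stats::cov(y, x) else sum(x * y)
    ss_y <- if (intercept) stats::var(y) else sum(y * y)
    ss_x <- if (intercept) stats::var(x) else sum(x * x)
    # the estimator divides by the x-y covariance; flag it unstable when
    # the correlation it rests on is negligible (early training, baseline)
    unstable <- abs(denom) < 0.1 * sqrt(ss_x * ss_y)
    slope <- if (abs(denom) < 1e-300) NA_real_ else ss_y / denom
  } else if (method == "deming") {
    # orthogonal regression (error-variance ratio 1), closed form
    xc <- x - mean(x); yc <- y - mean(y)
    sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
    if (sxy == 0 && syy <= sxx) {
      slope <- 0
    } else {
      slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    }
  } else { # pca: ratio of leading principal-component loadings
    m <- cbind(x, y)
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    load <- pc$rotation[, 1]
    if (abs(load[1]) < 1e-12) stop("degenerate leading component")
    slope <- load[2] / load[1]
  }
  structure(list(adaptation_index = unname(slope), r_squared = unname(r2),
                 method = method, unstable = unstable),
            class = "adaptation_measure")
}

#' Mid-movement force
#'
#' Mean lateral force over a `window`-second window centered at the
#' peak longitudinal speed (default 250 ms, i.e. -125 ms to +125 ms
#' around the peak); a secondary, regression-free measure of adaptation.
#'
#' @param trace A `force_trace`.
#' @param window Window width in seconds (default 0.25).
#' @return Mean force in newtons.
#' @export
mid_movement_force <- function(trace, window = 0.25) {
  stopifnot(inherits(trace, "force_trace"))
  v <- trace$longitudinal_velocity
  # median-filtered peak localization; raw speed breaks filter ties so a
  # clean symmetric profile localizes at its true peak
  f <- stats::runmed(v, 5)
  cand <- which(f >= max(f) - 1e-12)
  peak <- cand[which.max(v[cand])]
  dt <- trace$time[2] - trace$time[1]
  half <- round(window / 2 / dt)
  idx <- (peak - half):(peak + half)
  if (min(idx) < 1 || max(idx) > length(v))
    stop("mid-movement window exceeds the trace bounds")
  mean(trace$lateral_force[idx])
}

#' Sign-standardize adaptation values
#'
#' Puts all subjects and phases on one sign convention so group learning
#' curves are continuous across the A-to-B transition: values from
#' counter-clockwise-field subjects are negated (their force patterns
#' mirror the clockwise convention), and Task B values are negated once
#' more because the ideal pattern flips sign at the task transition
#' (a subject fully adapted to Task B reads -1 on the Task A
#' convention).
#'
#' @param values Numeric adaptation values (slopes regressed against the
#'   current task's ideal pattern, in the clockwise-subject frame).
#' @param field_direction `"CW"` or `"CCW"` (Task A field direction of
#'   the subject), recycled.
#' @param phase `"baseline"`, `"taskA"` or `"taskB"`, recycled.
#' @return Oriented values.
#' @export
orient <- function(values, field_direction, phase) {
  if (!all(field_direction %in% c("CW", "CCW")))
    stop("`field_direction` must be 'CW' or 'CCW'")
  if (!all(phase %in% c("baseline", "taskA", "taskB")))
    stop("unknown phase label")
  sgn <- ifelse(rep_len(field_direction, length(values)) == "CCW", -1, 1) *
    ifelse(rep_len(phase, length(values)) == "taskB", -1, 1)
  values * sgn
}

#' Write or read force traces as long-format CSV
#'
#' Columns: `subject`, `trial`, `phase`, `field_direction`,
#' `sample_index`, `time_s`, `lateral_force_N`,
#' `longitudinal_velocity_m_s`.
#'
#' @param traces List of `force_trace` objects.
#' @param path File path.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(traces, function(tr)
    data.frame(subject = tr$subject, trial = tr$trial, phase = tr$phase,
               field_direction = tr$field_direction,
               sample_index = seq_along(tr$time), time_s = tr$time,
               lateral_force_N = tr$lateral_force,
               longitudinal_velocity_m_s = tr$longitudinal_velocity,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_keys <- interaction(d$subject, d$trial, drop = TRUE)
  lapply(split(d, split_keys), function(g) {
    g <- g[order(g$sample_index), ]
    force_trace(g$time_s, g$lateral_force_N, g$longitudinal_velocity_m_s,
                subject = g$subject[1], trial = g$trial[1],
                phase = g$phase[1], field_direction = g$field_direction[1],
                check = FALSE)
  })
}
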