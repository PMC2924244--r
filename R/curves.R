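#' Learning curves
#'
#' A learning curve is a sequence of adaptation values indexed by trial.
#' Trial indices count *completed perturbation trials*, so index 0 is a
#' naive learner with adaptation 0 and index `k` is the adaptation
#' carried after `k` trials. That convention makes the zero origin of an
#' initial-learning curve and of a zero-crossing-aligned opposite
#' curve coincide, which is what allows learning rates to be compared
#' from a common performance level. Indices may be fractional after
#' alignment.
#'
#' @param trial Numeric vector, strictly increasing.
#' @param value Numeric vector of adaptation values.
#' @param group,phase,subject Optional metadata strings.
#' @return A data frame of class `learning_curve` with columns `trial`
#'   and `value`.
#' @export
learning_curve <- function(trial, value, group = NA_character_,
                           phase = NA_character_, subject = NA_character_) {
  if (length(trial) != length(value)) stop("`trial` and `value` lengths differ")
  if (length(trial) == 0L) stop("empty curve")
  if (any(diff(trial) <= 0)) stop("`trial` must be strictly increasing")
  if (!all(is.finite(value))) stop("curve values must be finite")
  structure(data.frame(trial = as.numeric(trial), value = as.numeric(value)),
            class = c("learning_curve", "data.frame"),
            group = group, phase = phase, subject = subject)
}

#' Extract a learning curve from a state trajectory
#'
#' Converts a simulated trajectory into the completed-trial curve
#' convention used by all curve operations. For the selected phases, a
#' trial at position `p` (1-based within the selection) contributes the
#' pre-update state as the adaptation after `p - 1` trials; if the
#' selection runs to the end of the trajectory the final post-update
#' state is appended as the last index.
#'
#' @param trajectory A `state_trajectory` from [simulate_two_state()] or
#'   [simulate_single_process()].
#' @param phases Character vector of phases to keep (default the two
#'   task phases).
#' @param observe `"all"` records every trial; `"probes"` keeps only the
#'   error-clamp trials, emulating what is experimentally observable.
#' @return A [learning_curve()].
#' @export
trajectory_curve <- function(trajectory, phases = c("taskA", "taskB"),
                             observe = c("all", "probes")) {
  stopifnot(inherits(trajectory, "state_trajectory"))
  observe <- match.arg(observe)
  sel <- which(trajectory$phase %in% phases)
  if (length(sel) == 0L) stop("no trials in the requested phases")
  idx <- seq_along(sel) - 1
  val <- trajectory$x_net[sel]
  if (observe == "probes") {
    keep <- trajectory$kind[sel] == "clamp"
    if (!any(keep)) stop("no clamp probes in the requested phases")
    idx <- idx[keep]; val <- val[keep]
  } else if (sel[length(sel)] == nrow(trajectory)) {
    idx <- c(idx, length(sel))
    val <- c(val, attr(trajectory, "x_fast_end") + attr(trajectory, "x_slow_end"))
  }
  learning_curve(idx, val, phase = paste(phases, collapse = "+"))
}

#' Interpolate a curve onto a trial grid
#'
#' Linear interpolation of the curve's values onto the requested trial
#' grid; extrapolation beyond the curve's span is refused.
#'
#' @param curve A [learning_curve()].
#' @param grid Numeric vector of trial indices within the curve's span.
#' @return A [learning_curve()] on `grid`.
#' @export
interpolate_curve <- function(curve, grid) {
  stopifnot(inherits(curve, "learning_curve"))
  rng <- range(curve$trial)
  if (any(grid < rng[1] - 1e-9) || any(grid > rng[2] + 1e-9))
    stop(sprintf("grid [%g, %g] extends beyond the curve span [%g, %g]",
                 min(grid), max(grid), rng[1], rng[2]))
  if (nrow(curve) == 1L) {
    v <- rep(curve$value, length(grid))
  } else {
    v <- stats::approx(curve$trial, curve$value, xout = grid, rule = 1)$y
    v[is.na(v)] <- curve$value[match(grid[is.na(v)], curve$trial)]
  }
  learning_curve(grid, v, group = attr(curve, "group"),
                 phase = attr(curve, "phase"), subject = attr(curve, "subject"))
}

#' Centered moving average of a curve
#'
#' Used for display smoothing of group learning curves (the
#' interference metric itself is computed on unsmoothed curves). Edges
#' are truncated to the available points.
#'
#' @param curve A [learning_curve()].
#' @param window Odd window width (default 3).
#' @return A smoothed [learning_curve()].
#' @export
moving_average <- function(curve, window = 3L) {
  stopifnot(inherits(curve, "learning_curve"))
  if (window < 1 || window %% 2 == 0) stop("`window` must be odd and >= 1")
  h <- (window - 1L) %/% 2L
  n <- nrow(curve)
  v <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - h):min(n, i + h)
    mean(curve$value[j])
  }, 0)
  learning_curve(curve$trial, v, group = attr(curve, "group"),
                 phase = attr(curve, "phase"), subject = attr(curve, "subject"))
}

#' Locate the zero-crossing of an opposite-learning segment
#'
#' Finds the (fractional, linearly interpolated) trial at which the
#' adaptation returns to baseline during opposite learning. Only
#' positive-to-negative crossings are considered; a value exactly 0 at a
#' recorded trial counts as a crossing at that trial. If the curve dips
#' below zero, rises above it and dips again, the `"last"` rule (the
#' default) takes the final crossing; `"first_last_average"` averages
#' the first and last crossing locations.
#'
#' @param curve A [learning_curve()] covering the opposite-learning
#'   segment.
#' @param rule `"last"` or `"first_last_average"`.
#' @param from Optional trial index: crossings before it are ignored
#'   (use the Task B onset index to restrict the search to Task B).
#' @return The crossing location (fractional trial index).
#' @export
find_zero_crossing <- function(curve, rule = c("last", "first_last_average"),
                               from = NULL) {
  stopifnot(inherits(curve, "learning_curve"))
  rule <- match.arg(rule)
  tr <- curve$trial; v <- curve$value
  if (!is.null(from)) {
    keep <- tr >= from - 1e-9
    tr <- tr[keep]; v <- v[keep]
  }
  n <- length(v)
  if (n < 2L) stop("too few points to locate a crossing")
  # a value exactly 0 at the segment start counts as a crossing there
  # (e.g. the 0-trial control, whose opposite learning starts at rest)
  cross <- if (v[1] == 0 && v[2] <= 0) tr[1] else numeric(0)
  for (i in seq_len(n - 1L)) {
    if (v[i] > 0 && v[i + 1L] <= 0) {
      cross <- c(cross, tr[i] + (tr[i + 1L] - tr[i]) * v[i] / (v[i] - v[i + 1L]))
    }
  }
  if (length(cross) == 0L)
    stop("no positive-to-negative zero-crossing in the segment [",
         format(tr[1]), ", ", format(tr[n]), "]")
  if (rule == "last") cross[length(cross)]
  else (cross[1] + cross[length(cross)]) / 2
}

#' Rectify the opposite-learning curve at a zero-crossing
#'
#' Re-indexes the curve so the crossing becomes trial 0 and negates the
#' values: the result starts near 0 and grows positive, directly
#' comparable to an initial-learning curve.
#'
#' @param curve A [learning_curve()] (task-trial indexed).
#' @param crossing Crossing location from [find_zero_crossing()].
#' @return A [learning_curve()] with attribute `zero_crossing`.
#' @export
rectify_opposite <- function(curve, crossing) {
  stopifnot(inherits(curve, "learning_curve"))
  rng <- range(curve$trial)
  if (crossing < rng[1] || crossing > rng[2])
    stop("crossing lies outside the curve span")
  keep <- curve$trial > crossing + 1e-12
  out <- learning_curve(c(0, curve$trial[keep] - crossing),
                        c(0, -curve$value[keep]),
                        group = attr(curve, "group"), phase = "opposite",
                        subject = attr(curve, "subject"))
  attr(out, "zero_crossing") <- crossing
  out
}

#' Anterograde-interference metric
#'
#' The percent reduction of the rectified opposite-learning curve
#' relative to the initial-learning curve over the first `window`
#' trials: both curves are linearly interpolated onto trials
#' `1..window`, averaged, and the metric is
#' `ai = 1 - mean_opposite / mean_initial`. A value of 0 is no
#' interference; 1 is a complete lack of opposite learning. Because the
#' window mean is proportional to the area under the interpolated curve
#' over the same span, `method = "area"` (rectangle-rule area on the
#' unit grid) yields the identical metric; both are exposed.
#'
#' @param initial Initial-learning [learning_curve()] (zero origin at
#'   trial 0).
#' @param opposite_rectified Rectified opposite curve from
#'   [rectify_opposite()].
#' @param window Number of trials to average (default 25).
#' @param method `"mean"` (window mean) or `"area"` (area under the
#'   interpolated curve).
#' @return An object of class `ai_result`: list with `zero_crossing`,
#'   `mean_initial`, `mean_opposite`, `ai`, `window`.
#' @export
ai_metric <- function(initial, opposite_rectified, window = 25L,
                      method = c("mean", "area")) {
  method <- match.arg(method)
  grid <- seq_len(window)
  vi <- interpolate_curve(initial, grid)$value
  vo <- interpolate_curve(opposite_rectified, grid)$value
  if (method == "mean") {
    mi <- mean(vi); mo <- mean(vo)
  } else {
    # rectangle-rule area on the unit trial grid, normalized by the span
    mi <- sum(vi) * 1 / window
    mo <- sum(vo) * 1 / window
  }
  if (mi <= 0)
    stop("mean initial learning is not positive; the metric is undefined")
  structure(list(zero_crossing = attr(opposite_rectified, "zero_crossing"),
                 mean_initial = mi, mean_opposite = mo,
                 ai = 1 - mo / mi, window = as.integer(window),
                 method = method),
            class = "ai_result")
}

#' @export
print.ai_result <- function(x, ...) {
  cat(sprintf(
    "anterograde interference: ai = %.4f (window %d, crossing at %s)\n",
    x$ai, x$window,
    if (is.null(x$zero_crossing)) "NA" else format(round(x$zero_crossing, 2))))
  invisible(x)
}

#' Final learning level
#'
#' Mean adaptation over the probe values falling in the last
#' `fraction` of the initial-training trials: the window is
#' `[floor((1 - fraction) * n_trials), n_trials]`, inclusive (for a
#' 13-trial exposure and the default fraction this is trials 9-13).
#'
#' @param curve A [learning_curve()] whose trial indices count Task A
#'   trials.
#' @param n_trials Task A duration on the same trial axis as `curve`.
#' @param fraction Final fraction of training to average (default 0.3).
#' @return Mean adaptation over the window.
#' @export
final_learning <- function(curve, n_trials, fraction = 0.3) {
  stopifnot(inherits(curve, "learning_curve"))
  if (n_trials <= 0) stop("`n_trials` must be positive")
  lo <- floor((1 - fraction) * n_trials)
  keep <- curve$trial >= lo & curve$trial <= n_trials
  if (!any(keep))
    stop(sprintf("no curve points in the final-learning window [%g, %g]",
                 lo, n_trials))
  mean(curve$value[keep])
}

#' Task-onset-aligned alternatives to the interference metric
#'
#' Raw adaptation level `k` trials after Task B onset, and the change in
#' adaptation between onset and trial `k` (both linearly interpolated).
#'
#' @param curve A [learning_curve()] spanning Task B.
#' @param k Trials after onset (default 50).
#' @param onset Trial index of Task B onset on the curve's axis.
#' @return Named numeric vector `(adaptation_at_k, adaptation_change)`.
#' @export
onset_aligned_metrics <- function(curve, k = 50, onset) {
  stopifnot(inherits(curve, "learning_curve"))
  if (max(curve$trial) < onset + k)
    stop("Task B segment shorter than ", k, " trials")
  v <- interpolate_curve(curve, c(onset, onset + k))$value
  c(adaptation_at_k = v[2], adaptation_change = v[2] - v[1])
}

#' Fit a saturating-exponential time constant to a learning curve
#'
#' Least-squares fit of `value(t) = asymptote * (1 - exp(-t / tau))`
#' with `t` measured from the alignment origin. For a given `tau` the
#' asymptote is solved in closed form, so the fit reduces to a seeded
#' multi-start 1-D search over `log(tau)`.
#'
#' @param curve A [learning_curve()] (trial 0 = alignment origin).
#' @param tau_range Search range for the time constant, in trials.
#' @param n_starts Number of multi-start intervals.
#' @return List with `tau`, `asymptote`, `sse`, `converged`.
#' @export
fit_time_constant <- function(curve, tau_range = c(0.5, 1000), n_starts = 8L) {
  stopifnot(inherits(curve, "learning_curve"))
  if (nrow(curve) < 5L) stop("need at least 5 points")
  if (stats::sd(curve$value) == 0) stop("curve is constant; no time constant")
  t <- curve$trial; y <- curve$value
  sse_at <- function(log_tau) {
    m <- 1 - exp(-t / exp(log_tau))
    denom <- sum(m^2)
    if (denom < 1e-300) return(list(sse = sum(y^2), a = 0))
    a <- sum(y * m) / denom
    list(sse = sum((y - a * m)^2), a = a)
  }
  lo <- log(tau_range[1]); hi <- log(tau_range[2])
  edges <- seq(lo, hi, length.out = n_starts + 1L)
  best <- NULL
  for (i in seq_len(n_starts)) {
    o <- stats::optimize(function(lt) sse_at(lt)$sse, c(edges[i], edges[i + 1L]),
                         tol = 1e-12)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  fit <- sse_at(best$minimum)
  tau <- exp(best$minimum)
  converged <- tau > tau_range[1] * 1.001 && tau < tau_range[2] * 0.999
  list(tau = tau, asymptote = fit$a, sse = fit$sse, converged = converged)
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean, used to compare the
#' across-subject reliability of interference metrics.
#'
#' @param values Numeric vector.
#' @return `sd(values) / mean(values)`.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("mean is zero; coefficient of variation undefined")
  stats::sd(values) / m
}

#' Pointwise mean of several learning curves
#'
#' Interpolates every curve onto `grid` and averages pointwise; grid
#' points outside a curve's span are skipped for that curve (so short
#' initial-learning curves still contribute where they have data).
#'
#' @param curves List of [learning_curve()] objects.
#' @param grid Trial grid for the aggregate.
#' @return A [learning_curve()] on the grid points covered by at least
#'   one curve.
#' @export
aggregate_curves <- function(curves, grid) {
  stopifnot(length(curves) > 0L)
  acc <- matrix(NA_real_, nrow = length(curves), ncol = length(grid))
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    inside <- grid >= min(cv$trial) - 1e-9 & grid <= max(cv$trial) + 1e-9
    if (any(inside))
      acc[i, inside] <- interpolate_curve(cv, grid[inside])$value
  }
  covered <- colSums(!is.na(acc)) > 0
  if (!any(covered)) stop("no curve covers any grid point")
  learning_curve(grid[covered], colMeans(acc[, covered, drop = FALSE],
                                         na.rm = TRUE),
                 group = "aggregate")
}

#' Write a set of learning curves as CSV
#'
#' Long format with columns `group`, `subject`, `phase`, `trial`,
#' `value`.
#'
#' @param curves List of [learning_curve()] objects.
#' @param path File path.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- lapply(curves, function(cv)
    data.frame(group = attr(cv, "group"), subject = attr(cv, "subject"),
               phase = attr(cv, "phase"), trial = cv$trial, value = cv$value,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
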