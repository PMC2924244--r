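#' One update of the two-process learner
#'
#' Applies a single trial of the state-space recursion. On a `field`
#' trial the motor error is `disturbance - (x_fast + x_slow)` and both
#' states update as `x' = A * x + B * error`. On a `null` trial the
#' disturbance is absent, so the error is `-(x_fast + x_slow)` and the
#' same learning rule applies. On a `clamp` trial the kinematic error is
#' eliminated, so the error is 0 and the states purely decay by their
#' retention factors.
#'
#' @param x_fast,x_slow Current fast and slow states.
#' @param params A [two_state_params()] object.
#' @param disturbance Normalized disturbance level for this trial.
#' @param kind One of `"field"`, `"clamp"`, `"null"`.
#' @return A list with `x_fast`, `x_slow` (updated states) and `error`.
#' @examples
#' p <- default_two_state_params()
#' step_two_state(0, 0, p, disturbance = 1, kind = "field")
#' @export
step_two_state <- function(x_fast, x_slow, params, disturbance, kind) {
  stopifnot(inherits(params, "two_state_params"))
  kind <- match.arg(kind, c("field", "clamp", "null"))
  vals <- c(x_fast = x_fast, x_slow = x_slow, disturbance = disturbance)
  if (!all(is.finite(vals)))
    stop("non-finite input: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  v <- as_two_state_vector(params)
  if (kind == "clamp") {
    list(x_fast = v[1] * x_fast, x_slow = v[3] * x_slow, error = 0)
  } else {
    d <- if (kind == "null") 0 else disturbance
    e <- d - (x_fast + x_slow)
    list(x_fast = v[1] * x_fast + v[2] * e,
         x_slow = v[3] * x_slow + v[4] * e,
         error = e)
  }
}

# shared driver for the compiled recursion
run_simulation <- function(v, schedule, initial_state, state_noise,
                           clamp_mode, bound) {
  stopifnot(inherits(schedule, "disturbance_schedule"))
  kind_code <- match(schedule$kind, c("field", "clamp", "null")) - 1L
  if (anyNA(kind_code)) stop("invalid trial kind in schedule")
  if (!all(is.finite(initial_state))) stop("non-finite initial state")
  noise <- if (is.null(state_noise)) numeric(0) else state_noise
  .simulate_cpp(v[1], v[2], v[3], v[4],
                as.numeric(schedule$disturbance), kind_code,
                initial_state[1], initial_state[2],
                noise, clamp_mode, bound)
}

#' Simulate the two-process model over a schedule
#'
#' Runs the trial-by-trial recursion over a [disturbance_schedule()].
#' The recorded states follow the pre-update convention: row `n` holds
#' the state that produced trial `n`'s motor output, so `x_net[1] = 0`
#' for a naive learner. The post-update state after the final trial is
#' attached as attributes `x_fast_end`/`x_slow_end`.
#'
#' @param params A [two_state_params()] object.
#' @param schedule A [disturbance_schedule()].
#' @param initial_state Length-2 numeric, the starting
#'   `(x_fast, x_slow)`.
#' @param clamp_mode `"decay"` (default): clamp trials force the error
#'   to 0 and the states decay by their retention factors; `"skip"`:
#'   clamp trials leave the states untouched.
#' @param bound Divergence guard: simulation aborts, naming the trial,
#'   if `|x_net|` exceeds it.
#' @return A data frame of class `state_trajectory` with columns
#'   `trial`, `phase`, `kind`, `disturbance`, `x_fast`, `x_slow`,
#'   `x_net`, `error`.
#' @examples
#' traj <- simulate_two_state(default_two_state_params(),
#'                            ab_schedule(112, 115))
#' tail(traj)
#' @export
simulate_two_state <- function(params, schedule, initial_state = c(0, 0),
                               clamp_mode = c("decay", "skip"), bound = 10) {
  stopifnot(inherits(params, "two_state_params"))
  clamp_mode <- match.arg(clamp_mode)
  res <- run_simulation(as_two_state_vector(params), schedule, initial_state,
                        NULL, if (clamp_mode == "decay") 0L else 1L, bound)
  out <- data.frame(trial = schedule$trial, phase = schedule$phase,
                    kind = schedule$kind, disturbance = schedule$disturbance,
                    x_fast = res$x_fast, x_slow = res$x_slow,
                    x_net = res$x_net, error = res$error,
                    stringsAsFactors = FALSE)
  structure(out, class = c("state_trajectory", "data.frame"),
            x_fast_end = res$x_fast_end, x_slow_end = res$x_slow_end,
            params = params)
}

#' Simulate a single-process learner over a schedule
#'
#' Identical contract to [simulate_two_state()] but with one adaptive
#' state, so `x_net = x`. The returned trajectory keeps the `x_fast`
#' column for the state and sets `x_slow` to 0 so downstream code is
#' agnostic to the number of processes.
#'
#' @param params A [process_params()] object.
#' @inheritParams simulate_two_state
#' @return A `state_trajectory` data frame.
#' @export
simulate_single_process <- function(params, schedule, initial_state = 0,
                                    clamp_mode = c("decay", "skip"),
                                    bound = 10) {
  stopifnot(inherits(params, "process_params"))
  clamp_mode <- match.arg(clamp_mode)
  v <- c(params$retention, params$learning_rate, 1, 0)  # inert second state
  res <- run_simulation(v, schedule, c(initial_state[1], 0), NULL,
                        if (clamp_mode == "decay") 0L else 1L, bound)
  out <- data.frame(trial = schedule$trial, phase = schedule$phase,
                    kind = schedule$kind, disturbance = schedule$disturbance,
                    x_fast = res$x_fast, x_slow = res$x_slow,
                    x_net = res$x_net, error = res$error,
                    stringsAsFactors = FALSE)
  structure(out, class = c("state_trajectory", "data.frame"),
            x_fast_end = res$x_fast_end, x_slow_end = res$x_slow_end,
            params = params)
}

#' Fixed point of the field-trial recursion
#'
#' Under a constant disturbance `f` the model converges to a closed-form
#' steady state: with `g_i = B_i / (1 - A_i)`, the asymptotic error is
#' `e = f / (1 + g_fast + g_slow)` and each state settles at `g_i * e`.
#' Used as an independent oracle for long simulations.
#'
#' @param params A [two_state_params()] or [process_params()] object.
#' @param f Constant disturbance level.
#' @return For two-state parameters, a named numeric vector
#'   `(x_fast, x_slow, x_net)`; for a single process, the scalar
#'   steady state `f * B / (1 - A + B)`.
#' @export
steady_state <- function(params, f) {
  if (inherits(params, "process_params")) {
    if (params$retention >= 1 && params$learning_rate > 0)
      stop("no fixed point: retention = 1 with a nonzero learning rate")
    return(f * params$learning_rate /
             (1 - params$retention + params$learning_rate))
  }
  stopifnot(inherits(params, "two_state_params"))
  v <- as_two_state_vector(params)
  if (any(v[c(1, 3)] >= 1 & v[c(2, 4)] > 0))
    stop("no fixed point: retention = 1 with a nonzero learning rate")
  g_f <- v[2] / (1 - v[1])
  g_s <- v[4] / (1 - v[3])
  e <- f / (1 + g_f + g_s)
  c(x_fast = g_f * e, x_slow = g_s * e, x_net = (g_f + g_s) * e)
}

#' Write or read a state trajectory as CSV
#'
#' Columns: `trial`, `x_fast`, `x_slow`, `x_net`, `error`.
#'
#' @param trajectory A `state_trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "state_trajectory"))
  utils::write.csv(
    trajectory[, c("trial", "x_fast", "x_slow", "x_net", "error")],
    path, row.names = FALSE)
  invisible(path)
}
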