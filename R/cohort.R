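#' Configuration for a synthetic cohort
#'
#' Bundles everything needed to generate complete synthetic subject
#' datasets: the group specifications, the population-level model
#' parameters, the noise model, and the reach kinematics. Defaults
#' emulate the study conditions: 10 cm / 500 ms reaches sampled at
#' 200 Hz in 2.25 s probe windows, a full-strength field of 15 N s/m,
#' and noise levels chosen to produce group learning curves with
#' realistic across-subject variability.
#'
#' @param groups Named list of [group_spec()]s (default
#'   [standard_groups()]).
#' @param params Population [two_state_params()].
#' @param subject_jitter_sd Relative SD of the per-subject lognormal
#'   parameter jitter (default 0.2); jittered draws violating the
#'   parameter invariants are resampled.
#' @param state_noise_sd SD of the zero-mean motor-output noise added to
#'   `x_net` on every trial (default 0.05, unitless adaptation).
#' @param trace_noise_sd SD of the smooth force-trace noise in newtons
#'   (default 0.3).
#' @param static_component_gain Amplitude (newtons) of the inappropriate
#'   static force component at the end of the movement, scaled by
#'   `1 - |x_net|` so it fades with learning (default 1.5).
#' @param reach_length,reach_duration Reach kinematics (0.1 m, 0.5 s).
#' @param sample_rate Trace sampling rate in Hz (default 200).
#' @param field_gain Full-strength field gain in N s/m (default 15).
#' @param seed Integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = standard_groups(),
                          params = default_two_state_params(),
                          subject_jitter_sd = 0.2,
                          state_noise_sd = 0.05,
                          trace_noise_sd = 0.3,
                          static_component_gain = 1.5,
                          reach_length = 0.1, reach_duration = 0.5,
                          sample_rate = 200, field_gain = 15,
                          seed = 1L) {
  sds <- c(subject_jitter_sd, state_noise_sd, trace_noise_sd,
           static_component_gain)
  if (any(sds < 0)) stop("noise magnitudes must be non-negative")
  stopifnot(inherits(params, "two_state_params"))
  structure(list(groups = groups, params = params,
                 subject_jitter_sd = subject_jitter_sd,
                 state_noise_sd = state_noise_sd,
                 trace_noise_sd = trace_noise_sd,
                 static_component_gain = static_component_gain,
                 reach_length = reach_length, reach_duration = reach_duration,
                 sample_rate = sample_rate, field_gain = field_gain,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Zero-noise variant of a cohort configuration
#'
#' Sets every stochastic or corrupting component (parameter jitter,
#' state noise, trace noise, static cross-talk) to zero, so measured
#' adaptation indices reproduce the noise-free model exactly; used for
#' pipeline-closure checks.
#'
#' @param config A [cohort_config()].
#' @return The modified config.
#' @export
zero_noise_config <- function(config) {
  config$subject_jitter_sd <- 0
  config$state_noise_sd <- 0
  config$trace_noise_sd <- 0
  config$static_component_gain <- 0
  config
}

# Lognormal per-subject parameter jitter with invariant-respecting
# resampling. Learning rates are jittered multiplicatively; retention is
# jittered on the forgetting rate (1 - A), the natural relative scale for
# a parameter pinned just below 1 (jittering A itself with rejection at 1
# would bias subject retention sharply downward).
jitter_params <- function(params, rel_sd, max_tries = 100L) {
  if (rel_sd == 0) return(params)
  v <- as_two_state_vector(params)
  for (k in seq_len(max_tries)) {
    z <- exp(stats::rnorm(4, 0, rel_sd))
    w <- c(1 - (1 - v[1]) * z[1], v[2] * z[2],
           1 - (1 - v[3]) * z[3], v[4] * z[4])
    ok <- all(w[c(1, 3)] > 0, w[c(1, 3)] <= 1, w[c(2, 4)] >= 0,
              w[c(2, 4)] < 1) && w[2] > w[4] && w[3] > w[1]
    if (ok)
      return(two_state_params(process_params(w[1], w[2]),
                              process_params(w[3], w[4])))
  }
  stop("could not draw valid subject parameters after ", max_tries, " tries")
}

# Smoothed-step shape for the static end-of-movement force component.
# The step rises just after the movement ends, where the longitudinal
# velocity is exactly zero, so the component is orthogonal to the ideal
# force pattern by construction (it perturbs the trace without biasing
# the regression index).
static_shape <- function(velocity_profile, reach_duration) {
  t <- velocity_profile$time
  mid <- t[(length(t) + 1L) %/% 2L]
  onset <- mid + reach_duration / 2 + 0.075
  stats::plogis((t - onset) / 0.025)
}

# smooth (low-pass filtered) trace noise with unit marginal SD
smooth_noise <- function(n, sample_rate, cutoff_hz = 10) {
  sigma <- sample_rate / (2 * pi * cutoff_hz)
  half <- ceiling(4 * sigma)
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sqrt(sum(kern^2))          # preserve marginal variance
  as.numeric(stats::filter(stats::rnorm(n + 2L * half), kern,
                           sides = 2))[half + seq_len(n)]
}

#' Simulate one synthetic subject
#'
#' Draws jittered subject parameters, builds the subject's probe
#' schedule, runs the two-process model with additive motor-output
#' noise, and emits a lateral force trace for every error-clamp trial:
#' the learned component (`output * ideal full-strength force`), the
#' fading static end-of-movement component, and smooth trace noise,
#' sign-flipped for counter-clockwise-field subjects. Fully reproducible
#' from `seed`.
#'
#' @param config A [cohort_config()].
#' @param spec The subject's [group_spec()].
#' @param subject Subject identifier string.
#' @param field_direction `"CW"` or `"CCW"`.
#' @param seed Integer seed for this subject.
#' @return An object of class `subject_record`: list with `subject`,
#'   `group`, `field_direction`, `params`, `schedule`, `trajectory`
#'   (including the noisy motor `output`), and `traces` (one
#'   `force_trace` per clamp trial).
#' @export
simulate_subject <- function(config, spec, subject = "s1",
                             field_direction = c("CW", "CCW"), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), inherits(spec, "group_spec"))
  field_direction <- match.arg(field_direction)
  with_local_seed(seed, {
    sub_params <- jitter_params(config$params, config$subject_jitter_sd)
    schedule <- build_schedule(spec, seed = NULL)   # uses the local RNG stream
    n <- nrow(schedule)
    noise <- stats::rnorm(n, 0, config$state_noise_sd)
    res <- run_simulation(as_two_state_vector(sub_params), schedule,
                          c(0, 0), noise, 0L, 10)
    traj <- data.frame(trial = schedule$trial, phase = schedule$phase,
                       kind = schedule$kind,
                       disturbance = schedule$disturbance,
                       x_fast = res$x_fast, x_slow = res$x_slow,
                       x_net = res$x_net, output = res$output,
                       error = res$error, stringsAsFactors = FALSE)
    vel <- minimum_jerk_velocity(config$reach_length, config$reach_duration,
                                 config$sample_rate)
    ideal_full <- ideal_force(vel, config$field_gain)
    shape <- static_shape(vel, config$reach_duration)
    dir_sign <- if (field_direction == "CCW") -1 else 1
    clamp_rows <- which(schedule$kind == "clamp")
    traces <- lapply(clamp_rows, function(i) {
      y <- traj$output[i]
      f <- y * ideal_full$force +
        config$static_component_gain * (1 - min(abs(y), 1)) * shape
      if (config$trace_noise_sd > 0)
        f <- f + config$trace_noise_sd *
          smooth_noise(length(f), config$sample_rate)
      force_trace(vel$time, dir_sign * f, vel$velocity,
                  subject = subject, trial = schedule$trial[i],
                  phase = schedule$phase[i],
                  field_direction = field_direction)
    })
    structure(list(subject = subject, group = spec$name,
                   field_direction = field_direction, params = sub_params,
                   schedule = schedule, trajectory = traj, traces = traces),
              class = "subject_record")
  })
}

#' Generate a full synthetic cohort
#'
#' One [simulate_subject()] record per subject per group, with field
#' directions alternating CW/CCW within each group and per-subject seeds
#' derived deterministically from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `synthetic_cohort`: a list of
#'   `subject_record`s with the config attached as an attribute.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' length(cohort)  # 58 subjects for the standard groups
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- sum(vapply(config$groups, `[[`, 0L, "n_subjects"))
  seeds <- with_local_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, n_total))
  records <- vector("list", n_total)
  k <- 0L
  for (spec in config$groups) {
    for (i in seq_len(spec$n_subjects)) {
      k <- k + 1L
      records[[k]] <- simulate_subject(
        config, spec, subject = sprintf("%s_s%02d", spec$name, i),
        field_direction = if (i %% 2L == 1L) "CW" else "CCW",
        seed = seeds[k])
    }
  }
  structure(records, class = "synthetic_cohort", config = config)
}

#' Measure a subject's adaptation from its force traces
#'
#' The analysis-side counterpart of [simulate_subject()]: averages the
#' last `n_baseline` pre-Task-A clamp traces into a baseline, subtracts
#' it from every probe trace, regresses each trace onto the
#' full-strength ideal pattern of its task (Task B's ideal is the
#' negated Task A pattern), and sign-standardizes the slopes with
#' [orient()]. Only the traces are consulted; the latent trajectory is
#' never read.
#'
#' @param record A `subject_record`.
#' @param config The [cohort_config()] (for the reach kinematics and
#'   field gain).
#' @param method Slope estimator passed to [adaptation_index()].
#' @param n_baseline Baseline clamp trials to average (default 5).
#' @return A data frame with one row per task probe: `subject`, `group`,
#'   `trial`, `phase`, `task_index` (completed task trials before the
#'   probe), `field_index` (completed field trials before the probe),
#'   `adaptation_index` (oriented), `r_squared`, `mid_force_N`
#'   (oriented), `method`.
#' @export
measure_subject <- function(record, config, method = "ols_yx",
                            n_baseline = 5L) {
  stopifnot(inherits(record, "subject_record"))
  vel <- minimum_jerk_velocity(config$reach_length, config$reach_duration,
                               config$sample_rate)
  ideal_full <- ideal_force(vel, config$field_gain)
  phases <- vapply(record$traces, `[[`, "", "phase")
  baseline <- baseline_average(record$traces[phases == "baseline"], n_baseline)
  task_rows <- which(record$schedule$phase %in% c("taskA", "taskB"))
  task_pos <- match(record$schedule$trial, record$schedule$trial[task_rows])
  field_cum <- cumsum(record$schedule$kind[task_rows] == "field")
  keep <- which(phases != "baseline")
  n <- length(keep)
  trial <- integer(n); phase <- character(n)
  slope <- numeric(n); r2 <- numeric(n); midf <- numeric(n)
  for (k in seq_len(n)) {
    tr <- baseline_subtract(record$traces[[keep[k]]], baseline)
    ideal_task <- ideal_full                    # Task B's ideal is the negation
    if (tr$phase == "taskB") ideal_task$force <- -ideal_task$force
    m <- adaptation_index(tr, ideal_task, method = method)
    trial[k] <- tr$trial; phase[k] <- tr$phase
    slope[k] <- m$adaptation_index; r2[k] <- m$r_squared
    midf[k] <- mid_movement_force(tr)
  }
  data.frame(subject = record$subject, group = record$group,
             trial = trial, phase = phase,
             task_index = task_pos[trial] - 1L,
             field_index = field_cum[task_pos[trial]],
             adaptation_index = orient(slope, record$field_direction, phase),
             r_squared = r2,
             # raw force is already sign-continuous across the A->B
             # transition; only the CW/CCW standardization applies
             mid_force_N = orient(midf, record$field_direction, "taskA"),
             method = method, stringsAsFactors = FALSE)
}

#' Measured learning curve of one subject
#'
#' Converts the oriented probe measurements into a [learning_curve()] on
#' the completed-task-trial axis (a probe at task position `p` reflects
#' the adaptation after `p - 1` task trials).
#'
#' @param measures Output of [measure_subject()].
#' @return A [learning_curve()].
#' @export
measured_curve <- function(measures) {
  m <- measures[order(measures$task_index), ]
  learning_curve(m$task_index, m$adaptation_index,
                 group = m$group[1], phase = "taskA+taskB",
                 subject = m$subject[1])
}

#' Write a cohort manifest
#'
#' JSON record of the configuration and derived per-subject metadata so
#' a cohort can be regenerated exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path File path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  config <- attr(cohort, "config")
  manifest <- list(
    seed = config$seed,
    params = as_two_state_vector(config$params),
    noise = list(subject_jitter_sd = config$subject_jitter_sd,
                 state_noise_sd = config$state_noise_sd,
                 trace_noise_sd = config$trace_noise_sd,
                 static_component_gain = config$static_component_gain),
    subjects = lapply(cohort, function(r)
      list(subject = r$subject, group = r$group,
           field_direction = r$field_direction)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
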