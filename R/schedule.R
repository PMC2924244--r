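#' Disturbance schedules
#'
#' A disturbance schedule is the trial-by-trial description of an
#' experiment: one row per trial with the normalized disturbance level
#' (`+1` is the full-strength field of Task A, `-1` the opposite field of
#' Task B, `+0.5` a half-strength field), the trial kind (`field`,
#' `clamp` or `null`) and the experimental phase (`baseline`, `taskA`,
#' `taskB`).
#'
#' @param disturbance Numeric vector of normalized field levels.
#' @param kind Character vector, each element one of `"field"`,
#'   `"clamp"`, `"null"`.
#' @param phase Character vector, each element one of `"baseline"`,
#'   `"taskA"`, `"taskB"`.
#' @return A data frame of class `disturbance_schedule` with columns
#'   `trial`, `phase`, `kind`, `disturbance`.
#' @examples
#' disturbance_schedule(c(1, 1, -1), c("field", "clamp", "field"),
#'                      c("taskA", "taskA", "taskB"))
#' @export
disturbance_schedule <- function(disturbance, kind, phase) {
  n <- length(disturbance)
  if (n == 0L) stop("a schedule must contain at least one trial")
  if (length(kind) != n || length(phase) != n)
    stop("`disturbance`, `kind` and `phase` must have equal length")
  if (!all(is.finite(disturbance))) stop("disturbances must be finite")
  if (!all(kind %in% c("field", "clamp", "null")))
    stop("`kind` entries must be 'field', 'clamp' or 'null'")
  if (!all(phase %in% c("baseline", "taskA", "taskB")))
    stop("`phase` entries must be 'baseline', 'taskA' or 'taskB'")
  structure(data.frame(trial = seq_len(n), phase = phase, kind = kind,
                       disturbance = as.numeric(disturbance),
                       stringsAsFactors = FALSE),
            class = c("disturbance_schedule", "data.frame"))
}

#' Pure field-trial AB schedule
#'
#' The schedule used for model predictions: `n_a` field trials at
#' `+strength_a` (Task A) followed by `n_b` field trials at `strength_b`
#' (Task B), with no baseline and no clamp probes. Either task may be
#' empty (e.g. `n_a = 0` gives the initial-learning "0-trial" control).
#'
#' @param n_a,n_b Number of Task A / Task B field trials.
#' @param strength_a Normalized Task A field level (default `1`).
#' @param strength_b Normalized Task B field level (default `-1`).
#' @return A [disturbance_schedule()].
#' @export
ab_schedule <- function(n_a, n_b, strength_a = 1, strength_b = -1) {
  if (n_a < 0 || n_b < 0) stop("trial counts must be non-negative")
  if (n_a + n_b == 0) stop("schedule would be empty")
  disturbance_schedule(
    disturbance = c(rep(strength_a, n_a), rep(strength_b, n_b)),
    kind = rep("field", n_a + n_b),
    phase = c(rep("taskA", n_a), rep("taskB", n_b)))
}

#' Specification of one experimental group
#'
#' @param name Group label.
#' @param n_subjects Number of subjects.
#' @param taskA_trials Number of Task A field trials (clamp probes are
#'   additional trials, not counted here).
#' @param taskB_trials Number of Task B field trials.
#' @param taskA_strength Normalized Task A field level (`1` full
#'   strength, i.e. 15 N s/m; `0.5` half strength, 7.5 N s/m).
#' @param baseline_trials Number of baseline trials (default 160).
#' @param clamp_rate Fraction of task trials that are error-clamp probes
#'   (default 1/7).
#' @param baseline_clamp_rate Fraction of baseline trials that are
#'   error-clamp probes (default 0.10).
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, n_subjects, taskA_trials, taskB_trials,
                       taskA_strength = 1, baseline_trials = 160,
                       clamp_rate = 1 / 7, baseline_clamp_rate = 0.10) {
  if (taskA_trials < 0 || taskB_trials < 0 || baseline_trials < 0)
    stop("trial counts must be non-negative")
  if (n_subjects < 1) stop("`n_subjects` must be at least 1")
  if (clamp_rate < 0 || clamp_rate >= 1 ||
      baseline_clamp_rate < 0 || baseline_clamp_rate >= 1)
    stop("clamp rates must lie in [0, 1)")
  structure(list(name = as.character(name), n_subjects = as.integer(n_subjects),
                 taskA_trials = as.integer(taskA_trials),
                 taskB_trials = as.integer(taskB_trials),
                 taskA_strength = taskA_strength,
                 baseline_trials = as.integer(baseline_trials),
                 clamp_rate = clamp_rate,
                 baseline_clamp_rate = baseline_clamp_rate),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("group '%s': %d subjects, Task A %d trials at %+.2g, Task B %d trials at -1\n",
              x$name, x$n_subjects, x$taskA_trials, x$taskA_strength, x$taskB_trials))
  invisible(x)
}

#' The six study groups
#'
#' The five full-strength groups (Task A durations 13, 41, 112, 230 and
#' 369 field trials, with 14/9/9/9/9 subjects and Task B durations
#' 116/114/113/112/120) plus the reduced group (8 subjects, 230 Task A
#' trials at half strength, Task B mirroring the full 230 group).
#'
#' @return A named list of [group_spec()] objects.
#' @export
standard_groups <- function() {
  specs <- list(
    group_spec("full13",     14,  13, 116),
    group_spec("full41",      9,  41, 114),
    group_spec("full112",     9, 112, 113),
    group_spec("full230",     9, 230, 112),
    group_spec("full369",     9, 369, 120),
    group_spec("reduced230",  8, 230, 112, taskA_strength = 0.5))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# Place clamp probes among perturbation trials. Probes are *extra*
# trials: each consecutive block of (block - 1) perturbation trials gets
# one probe inserted, so a rate of 1/7 means blocks of 6 field trials
# plus one clamp (13 field trials -> 3 probes -> 16 trials total). With
# placement = "jittered" the probe position inside each block is drawn
# uniformly (avoiding two adjacent probes); "exact" puts it at the end.
insert_clamps <- function(n_trials, rate, placement = c("jittered", "exact")) {
  placement <- match.arg(placement)
  if (rate <= 0 || n_trials == 0L)
    return(rep(FALSE, n_trials))
  per_block <- max(1L, round(1 / rate) - 1L)        # perturbation trials per block
  n_blocks <- ceiling(n_trials / per_block)
  is_clamp <- logical(0)
  prev_tail_gap <- Inf   # perturbation trials since the last probe
  remaining <- n_trials
  for (b in seq_len(n_blocks)) {
    m <- min(per_block, remaining)
    remaining <- remaining - m
    # probe goes after position p (0 = block start), p in 0..m
    if (placement == "exact") {
      p <- m
    } else {
      allowed <- 0:m
      if (prev_tail_gap == 0) allowed <- allowed[allowed > 0]  # no adjacent probes
      p <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    }
    block <- rep(FALSE, m)
    is_clamp <- c(is_clamp, append(block, TRUE, after = p))
    prev_tail_gap <- m - p
  }
  is_clamp
}

#' Build the full trial schedule for one group
#'
#' Baseline phase (`baseline_trials` null trials with ~10% clamp
#' probes), Task A (`taskA_trials` field trials at `+taskA_strength`
#' with probes interleaved at `clamp_rate`), Task B (`taskB_trials`
#' field trials at `-1` with probes at `clamp_rate`). Probes are extra
#' trials, not counted in the advertised task durations. Deterministic
#' given `seed`.
#'
#' @param spec A [group_spec()].
#' @param seed Integer seed for the probe-placement jitter.
#' @param placement `"jittered"` (default; one probe at a uniformly drawn
#'   position within each block) or `"exact"` (probe after every block).
#' @param include_baseline Set `FALSE` to omit the baseline phase.
#' @return A [disturbance_schedule()].
#' @examples
#' sched <- build_schedule(standard_groups()$full13, seed = 1)
#' table(sched$phase, sched$kind)
#' @export
build_schedule <- function(spec, seed = 1L,
                           placement = c("jittered", "exact"),
                           include_baseline = TRUE) {
  stopifnot(inherits(spec, "group_spec"))
  placement <- match.arg(placement)
  with_local_seed(seed, {
    phases <- list()
    if (include_baseline && spec$baseline_trials > 0L) {
      ic <- insert_clamps(round(spec$baseline_trials * (1 - spec$baseline_clamp_rate)),
                          spec$baseline_clamp_rate, placement)
      # baseline is defined by its total trial count; trim/pad to it
      ic <- ic[seq_len(min(length(ic), spec$baseline_trials))]
      phases$baseline <- data.frame(
        phase = "baseline", kind = ifelse(ic, "clamp", "null"),
        disturbance = 0)
    }
    if (spec$taskA_trials > 0L) {
      ic <- insert_clamps(spec$taskA_trials, spec$clamp_rate, placement)
      phases$taskA <- data.frame(
        phase = "taskA", kind = ifelse(ic, "clamp", "field"),
        disturbance = spec$taskA_strength)
    }
    if (spec$taskB_trials > 0L) {
      ic <- insert_clamps(spec$taskB_trials, spec$clamp_rate, placement)
      phases$taskB <- data.frame(
        phase = "taskB", kind = ifelse(ic, "clamp", "field"),
        disturbance = -1)
    }
    all <- do.call(rbind, phases)
    disturbance_schedule(all$disturbance, all$kind, all$phase)
  })
}

#' Read or write a schedule as CSV
#'
#' Columns: `trial`, `phase`, `kind`, `disturbance`.
#'
#' @param schedule A [disturbance_schedule()].
#' @param path File path.
#' @return `read_schedule_csv()` returns a [disturbance_schedule()];
#'   `write_schedule_csv()` returns `path` invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "disturbance_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  disturbance_schedule(d$disturbance, d$kind, d$phase)
}

# run expr with a local, restored RNG state
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}
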