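#' Fit the two-process model to a learning curve
#'
#' Constrained least squares: finds the retention/learning-rate pairs
#' minimizing the squared error between the model's adaptation curve on
#' `schedule` and the observed curve values at their trial indices
#' (completed-task-trial convention, matching [trajectory_curve()] and
#' [measured_curve()]). The constraints `0 < A < 1`, `0 <= B < 1`,
#' `B_fast > B_slow` and `A_slow > A_fast` are enforced by construction
#' through a logistic reparameterization, and the best of `n_starts`
#' seeded random initializations is returned.
#'
#' @param curve A [learning_curve()] of observed adaptation values
#'   (probe trials only), or a list of them (e.g. one per subject); the
#'   squared errors are pooled over all curves.
#' @param schedule The [disturbance_schedule()] the data came from; a
#'   list of schedules (matching `curve`) when subjects had individual
#'   probe placements.
#' @param n_starts Number of random restarts (default 20).
#' @param seed Integer seed for the restarts.
#' @param phases Phases of `schedule` the curves are indexed over.
#' @return An object of class `fit_result`: list with `params`
#'   ([two_state_params()]), `sse`, `n_starts`, `converged`.
#' @export
fit_two_state <- function(curve, schedule, n_starts = 20L, seed = 1L,
                          phases = c("taskA", "taskB")) {
  curves <- if (inherits(curve, "learning_curve")) list(curve) else curve
  schedules <- if (inherits(schedule, "disturbance_schedule"))
    rep(list(schedule), length(curves)) else schedule
  if (length(schedules) != length(curves))
    stop("`schedule` must be one schedule or one per curve")
  prep <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]; sc <- schedules[[i]]
    stopifnot(inherits(cv, "learning_curve"),
              inherits(sc, "disturbance_schedule"))
    sel <- which(sc$phase %in% phases)
    if (length(sel) == 0L) stop("schedule has no trials in the given phases")
    if (any(cv$trial < 0) || any(cv$trial > length(sel)))
      stop("curve indices fall outside the schedule's task span")
    list(dist = as.numeric(sc$disturbance[sel]),
         kind = match(sc$kind[sel], c("field", "clamp", "null")) - 1L,
         idx = cv$trial, obs = cv$value, n = length(sel))
  })
  unpack <- function(th) {
    a_s <- stats::plogis(th[1])
    a_f <- a_s * stats::plogis(th[2])        # A_f < A_s
    b_f <- stats::plogis(th[3])
    b_s <- b_f * stats::plogis(th[4])        # B_s < B_f
    c(a_f, b_f, a_s, b_s)
  }
  # model curve value at integer index k = pre-update state at trial k + 1
  # (the adaptation carried after k task trials); fractional indices are
  # linearly interpolated
  objective <- function(th) {
    v <- unpack(th)
    total <- 0
    for (pp in prep) {
      res <- tryCatch(
        .simulate_cpp(v[1], v[2], v[3], v[4], pp$dist, pp$kind, 0, 0,
                      numeric(0), 0L, 50),
        error = function(e) NULL)
      if (is.null(res)) return(1e10)
      path <- c(res$x_net, res$x_fast_end + res$x_slow_end)
      pred <- stats::approx(0:pp$n, path, xout = pp$idx)$y
      total <- total + sum((pp$obs - pred)^2)
    }
    total
  }
  best <- NULL
  with_local_seed(seed, {
    for (s in seq_len(n_starts)) {
      th0 <- c(stats::qlogis(stats::runif(1, 0.9, 0.9999)),
               stats::qlogis(stats::runif(1, 0.2, 0.95)),
               stats::qlogis(stats::runif(1, 0.02, 0.6)),
               stats::qlogis(stats::runif(1, 0.02, 0.6)))
      o <- tryCatch(
        stats::optim(th0, objective, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(o)) {
        o <- stats::optim(o$par, objective, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14))
        if (is.null(best) || o$value < best$value) best <- o
      }
    }
  })
  if (is.null(best)) stop("all optimization starts failed")
  v <- unpack(best$par)
  structure(list(params = two_state_params(process_params(v[1], v[2]),
                                           process_params(v[3], v[4])),
                 sse = best$value, n_starts = as.integer(n_starts),
                 converged = is.finite(best$value) && best$value < 1e10),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("two-process fit: sse = %.4g (%d starts)\n", x$sse, x$n_starts))
  print(x$params)
  invisible(x)
}

#' Subject-level bootstrap percentile confidence interval
#'
#' Resamples subjects with replacement `n` times, applies `statistic`
#' (a function mapping a list of subjects to a named numeric vector,
#' e.g. a per-group interference metric, possibly via a model refit),
#' and returns 2.5%/97.5% percentile intervals. Failed or non-finite
#' evaluations are counted; more than 10% failures is an error.
#'
#' @param subjects List of subject-level objects.
#' @param statistic A function mapping a list of subjects to a named
#'   numeric vector.
#' @param n Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_ci`: data frame with columns
#'   `statistic`, `point`, `lower`, `upper`, plus attributes
#'   `n_resamples` and `n_failed`.
#' @export
bootstrap_ci <- function(subjects, statistic, n = 1000L, seed = 1L) {
  if (length(subjects) < 2L) stop("need at least 2 subjects to bootstrap")
  point <- statistic(subjects)
  if (is.null(names(point))) names(point) <- paste0("stat", seq_along(point))
  draws <- matrix(NA_real_, nrow = n, ncol = length(point),
                  dimnames = list(NULL, names(point)))
  failed <- 0L
  with_local_seed(seed, {
    for (b in seq_len(n)) {
      idx <- sample.int(length(subjects), replace = TRUE)
      val <- tryCatch(statistic(subjects[idx]), error = function(e) NULL)
      if (is.null(val) || any(!is.finite(val))) failed <- failed + 1L
      else draws[b, ] <- val
    }
  })
  if (failed > 0.1 * n)
    stop(failed, " of ", n, " bootstrap evaluations failed")
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  structure(data.frame(statistic = names(point), point = unname(point),
                       lower = qs[1, ], upper = qs[2, ],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("bootstrap_ci", "data.frame"),
            n_resamples = as.integer(n), n_failed = failed)
}

#' Coefficient of determination between model and data
#'
#' Three variants of R^2 used to judge how well model predictions
#' account for observed values: `direct` compares them with no free
#' parameters (`1 - SS_res / SS_tot` with residuals `obs - pred`);
#' `regress_1dof` allows the best scaling of the predictions (slope
#' only); `regress_2dof` allows the best affine map (slope and offset).
#' By nesting, `regress_2dof >= regress_1dof >= direct`.
#'
#' @param pred,obs Numeric vectors of equal length (>= 2).
#' @param mode One of `"direct"`, `"regress_1dof"`, `"regress_2dof"`.
#' @return The R^2 value (can be negative for `direct` when the model
#'   does worse than the observed mean).
#' @export
r_squared <- function(pred, obs,
                      mode = c("direct", "regress_1dof", "regress_2dof")) {
  mode <- match.arg(mode)
  if (length(pred) != length(obs) || length(obs) < 2L)
    stop("`pred` and `obs` must have equal length >= 2")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("observations have zero variance")
  resid <- switch(mode,
    direct = obs - pred,
    regress_1dof = obs - (sum(pred * obs) / sum(pred^2)) * pred,
    regress_2dof = stats::lm.fit(cbind(1, pred), obs)$residuals)
  1 - sum(resid^2) / ss_tot
}

#' One-way analysis of variance across groups
#'
#' Standard between/within decomposition, computed with [stats::aov()].
#'
#' @param groups Named list of numeric vectors (one per group, each
#'   with at least 2 values).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("every group needs at least 2 values")
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, 0L))))
  tab <- summary(stats::aov(value ~ group, data = d))[[1]]
  list(F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
       p = tab[1, "Pr(>F)"])
}

#' Student t-tests
#'
#' Thin wrapper over [stats::t.test()] (equal-variance Student variant
#' for two samples) returning the statistic and p-value for the
#' one-sample, paired or unpaired two-sample cases.
#'
#' @param a Numeric vector.
#' @param b Optional second sample; omit for a one-sample test against
#'   `mu`.
#' @param mu Null value for the one-sample test (default 0).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param paired Paired two-sample test (default `FALSE`).
#' @return List with `t`, `df`, `p`.
#' @export
t_test <- function(a, b = NULL, mu = 0,
                   alternative = c("two.sided", "less", "greater"),
                   paired = FALSE) {
  alternative <- match.arg(alternative)
  res <- if (is.null(b))
    stats::t.test(a, mu = mu, alternative = alternative)
  else
    stats::t.test(a, b, alternative = alternative, paired = paired,
                  var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
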