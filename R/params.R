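#' Parameters of a single adaptive process
#'
#' A single adaptive process is the unit of the state-space learning
#' model: on every perturbation trial its state `x` is updated as
#' `x' = retention * x + learning_rate * error`. Retention is the
#' per-trial fraction of the state carried forward; the learning rate is
#' the per-trial gain on the motor error.
#'
#' @param retention Per-trial retention multiplier, in (0, 1].
#' @param learning_rate Per-trial error gain, in [0, 1).
#' @return An object of class `process_params`.
#' @examples
#' process_params(retention = 0.9923, learning_rate = 0.03)
#' @export
process_params <- function(retention, learning_rate) {
  if (!is.numeric(retention) || length(retention) != 1L || !is.finite(retention))
    stop("`retention` must be a single finite number")
  if (!is.numeric(learning_rate) || length(learning_rate) != 1L || !is.finite(learning_rate))
    stop("`learning_rate` must be a single finite number")
  if (retention <= 0 || retention > 1)
    stop("`retention` must satisfy 0 < retention <= 1, got ", retention)
  if (learning_rate < 0 || learning_rate >= 1)
    stop("`learning_rate` must satisfy 0 <= learning_rate < 1, got ", learning_rate)
  structure(list(retention = retention, learning_rate = learning_rate),
            class = "process_params")
}

#' Parameters of the two-process multi-rate learning model
#'
#' The model is the sum of two adaptive processes driven by the same
#' motor error: a fast process that learns quickly but forgets quickly,
#' and a slow process that learns slowly but retains well. That
#' structure is enforced here: the fast learning rate must exceed the
#' slow one, and the slow retention must exceed the fast one.
#'
#' @param fast,slow [process_params()] objects for the fast and slow
#'   process.
#' @return An object of class `two_state_params`.
#' @seealso [default_two_state_params()] for the package default set.
#' @examples
#' two_state_params(fast = process_params(0.57, 0.22),
#'                  slow = process_params(0.993, 0.016))
#' @export
two_state_params <- function(fast, slow) {
  if (!inherits(fast, "process_params") || !inherits(slow, "process_params"))
    stop("`fast` and `slow` must be process_params objects")
  if (!(fast$learning_rate > slow$learning_rate))
    stop("the fast learning rate must exceed the slow learning rate (B_f > B_s)")
  if (!(slow$retention > fast$retention))
    stop("the slow retention must exceed the fast retention (A_s > A_f)")
  structure(list(fast = fast, slow = slow), class = "two_state_params")
}

#' Default parameter set for the two-process model
#'
#' Retention/learning-rate values for the fast and slow process,
#' calibrated against the model predictions for the AB force-field
#' paradigm (a mean interference level of 0.54 across the four longest
#' full-strength training durations, and 0.33 for a half-strength
#' 230-trial exposure). They are close to the constrained fit reported
#' for the original spontaneous-recovery data from which the model was
#' proposed. Every simulation and pipeline function takes a parameter
#' object explicitly; this set is only a documented default.
#'
#' @return A [two_state_params()] object with
#'   `A_f = 0.57, B_f = 0.22, A_s = 0.993, B_s = 0.016`.
#' @export
default_two_state_params <- function() {
  two_state_params(fast = process_params(retention = 0.57, learning_rate = 0.22),
                   slow = process_params(retention = 0.993, learning_rate = 0.016))
}

#' Reference single-process control parameters
#'
#' A single-state learner with `A = 0.9923`, `B = 0.03`. Because a
#' one-state model has no internal bias left at the zero-crossing, it
#' predicts no anterograde interference; it is the control against
#' which the two-process predictions are compared.
#'
#' @return A [process_params()] object.
#' @export
default_single_params <- function() {
  process_params(retention = 0.9923, learning_rate = 0.03)
}

#' @export
print.process_params <- function(x, ...) {
  cat(sprintf("adaptive process: retention A = %.4g, learning rate B = %.4g\n",
              x$retention, x$learning_rate))
  invisible(x)
}

#' @export
print.two_state_params <- function(x, ...) {
  cat("two-process multi-rate model parameters\n")
  cat(sprintf("  fast: A_f = %.4g, B_f = %.4g\n",
              x$fast$retention, x$fast$learning_rate))
  cat(sprintf("  slow: A_s = %.4g, B_s = %.4g\n",
              x$slow$retention, x$slow$learning_rate))
  invisible(x)
}

# coerce a length-4 numeric (a_fast, b_fast, a_slow, b_slow) for internal use
as_two_state_vector <- function(params) {
  stopifnot(inherits(params, "two_state_params"))
  c(params$fast$retention, params$fast$learning_rate,
    params$slow$retention, params$slow$learning_rate)
}
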