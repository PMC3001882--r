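#' Response model constants
#'
#' The decision side of the observer: `beta_err` is the loss trade-off
#' (errors traded per second of delay; formally an error rate), `beta_sens`
#' the within-trial convergence rate of the belief toward its converged
#' value (sensitivity to post-hoc prediction error, 1/s), and `phi` the
#' precision of i.i.d. Gaussian reaction-time noise (1/s^2).
#'
#' @param beta_err,beta_sens,phi strictly positive reals.
#' @return an object of class `response_params`.
#' @export
response_params <- function(beta_err = 0.1, beta_sens = 1, phi = 1) {
  stopifnot(beta_err > 0, beta_sens > 0, phi > 0)
  structure(list(beta_err = beta_err, beta_sens = beta_sens, phi = phi),
            class = "response_params")
}

#' Loss function of the speed-accuracy trade-off
#'
#' A categorisation error costs one unit; waiting costs `beta_err` per
#' second.
#'
#' @param choice,category binary (0 = face, 1 = house).
#' @param t decision time in seconds (>= 0).
#' @param beta_err positive trade-off rate.
#' @return nonnegative loss.
#' @export
loss <- function(choice, category, t, beta_err) {
  if (any(t < 0)) stop("decision time must be nonnegative")
  as.numeric(choice != category) + beta_err * t
}

# signed prediction-error magnitude for the chosen category:
# positive when the belief moves toward the choice, negative on
# categorisation-error-sign trials
signed_dmu <- function(delta_mu, choice) {
  (2 * choice - 1) * delta_mu
}

#' Posterior risk as a function of decision time
#'
#' Expected loss of committing to `choice` at peristimulus time `t`, given
#' that the within-trial belief relaxes exponentially (rate `beta_sens`)
#' from the pre-stimulus prediction toward the converged posterior:
#' `rho(t) = dtil * exp(-beta_sens t) + beta_err * t`, where `dtil` is the
#' post-hoc prediction error `delta_mu = mu_x - xi` signed for the chosen
#' category (terms constant in `t` are dropped). The risk is convex in `t`
#' whenever the choice is consistent with the converged belief
#' (`dtil > 0`).
#'
#' @param delta_mu post-hoc prediction error in `[-1, 1]`.
#' @param choice binary choice (0 = face, 1 = house). Default 1.
#' @param t decision time(s), seconds (>= 0).
#' @param params a [response_params()].
#' @return risk value(s).
#' @export
posterior_risk <- function(delta_mu, t, params, choice = 1) {
  if (any(t < 0)) stop("decision time must be nonnegative")
  stopifnot(abs(delta_mu) <= 1)
  dtil <- signed_dmu(delta_mu, choice)
  dtil * exp(-params$beta_sens * t) + params$beta_err * t
}

#' Closed-form optimal reaction time
#'
#' The global minimiser of [posterior_risk()] over decision time, clipped
#' at zero: `t* = max(0, log(beta_sens * dtil / beta_err) / beta_sens)`,
#' and `t* = 0` whenever the prediction error carries the
#' categorisation-error sign (`dtil <= 0`).
#'
#' @inheritParams posterior_risk
#' @return optimal decision time(s) in seconds, `>= 0`.
#' @export
optimal_rt <- function(delta_mu, params, choice = 1) {
  dtil <- signed_dmu(delta_mu, choice)
  ifelse(dtil <= 0, 0,
         pmax(0, log(params$beta_sens * dtil / params$beta_err) /
                params$beta_sens))
}

#' Predicted reaction-time series from a recognition trace
#'
#' Per-trial optimal reaction time from the post-hoc prediction error
#' `mu_x - xi`, assuming the choice follows the converged belief (no
#' categorisation errors), so the signed prediction error equals
#' `|mu_x - xi|`.
#'
#' @param trace a `recognition_trace` from [run_recognition()].
#' @param params a [response_params()].
#' @return numeric vector of optimal reaction times (seconds).
#' @export
predicted_rt_series <- function(trace, params) {
  stopifnot(nrow(trace) >= 1L)
  .optimal_rt_series_cpp(trace$mu_x, trace$xi,
                         params$beta_err, params$beta_sens)
}

#' Simulate noisy reaction times
#'
#' Adds i.i.d. Gaussian noise of precision `phi` to a deterministic
#' reaction-time series.
#'
#' @param t_star deterministic optimal reaction times.
#' @param phi positive noise precision (1/s^2).
#' @param seed RNG seed.
#' @return numeric vector of observed reaction times.
#' @export
simulate_rts <- function(t_star, phi, seed = 1L) {
  stopifnot(phi > 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  t_star + stats::rnorm(length(t_star), 0, sqrt(1 / phi))
}

#' Weighted Gaussian reaction-time log-likelihood
#'
#' Sum of Gaussian log-densities of observed reaction times around their
#' predicted values, with per-trial precision `phi * weight`. Error trials
#' down-weighted to near-zero weight are thereby effectively removed.
#'
#' @param y observed reaction times.
#' @param t_star predicted reaction times (same length).
#' @param phi positive noise precision.
#' @param weights per-trial weights in (0, 1]; default all 1.
#' @return scalar log-likelihood.
#' @export
rt_loglik <- function(y, t_star, phi, weights = rep(1, length(y))) {
  stopifnot(length(y) == length(t_star), length(weights) == length(y))
  if (any(weights <= 0)) stop("weights must be positive")
  sum(0.5 * log(phi * weights / (2 * pi)) -
        0.5 * phi * weights * (y - t_star)^2)
}
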