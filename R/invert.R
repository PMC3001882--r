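#' Prior specification for response-model inversion
#'
#' Weakly informative log-normal priors on the perceptual and response
#' parameters (Gaussian moments on the natural-log scale) and a Gamma prior
#' on the reaction-time noise precision. Defaults: log-lambda mean 0
#' (dynamic) or 2 (static) with variance 10^2; log beta_err and
#' log beta_sens mean 0, variance 10^2; phi with prior mean 1e4 and a
#' weakly informative spread (shape 0.01, so the data dominate the
#' noise-precision posterior at any realistic noise level).
#'
#' @param model `"dynamic"` or `"static"` (sets the log-lambda prior mean).
#' @param mean,var length-3 Gaussian moments for
#'   `(log lambda, log beta_err, log beta_sens)`.
#' @param phi_mean,phi_var moments of the Gamma prior on phi.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(model = c("dynamic", "static"),
                       mean = NULL,
                       var = c(100, 100, 100),
                       phi_mean = 1e4, phi_var = 1e10) {
  model <- match.arg(model)
  if (is.null(mean)) mean <- c(if (model == "dynamic") 0 else 2, 0, 0)
  stopifnot(length(mean) == 3L, length(var) == 3L, all(var > 0),
            phi_mean > 0, phi_var > 0)
  structure(list(model = model,
                 mean = as.numeric(mean), var = as.numeric(var),
                 a0 = phi_mean^2 / phi_var, b0 = phi_mean / phi_var),
            class = "prior_spec")
}

#' Inversion settings
#'
#' @param tol outer-loop free-energy convergence tolerance.
#' @param max_iter maximum outer iterations.
#' @param fd_step central finite-difference step in log-parameter space.
#' @param n_starts number of multi-start restarts: up to five deterministic
#'   starts (a grid over log-lambda around the prior mean, each with a
#'   data-driven loss-parameter start), then seeded jitter.
#' @param jitter_sd standard deviation of the start jitter.
#' @param seed seed for the start jitter.
#' @param eta_face,eta_house,sigma_u fixed perceptual likelihood constants.
#' @param init_mean,init_var dynamic-model initial belief.
#' @return a list of settings.
#' @export
inversion_config <- function(tol = 1e-4, max_iter = 64L, fd_step = 1e-4,
                             n_starts = 5L, jitter_sd = 1, seed = 1L,
                             eta_face = -1, eta_house = 1, sigma_u = 0.5,
                             init_mean = 0, init_var = 1) {
  list(tol = tol, max_iter = as.integer(max_iter), fd_step = fd_step,
       n_starts = as.integer(n_starts), jitter_sd = jitter_sd,
       seed = as.integer(seed),
       eta_face = eta_face, eta_house = eta_house, sigma_u = sigma_u,
       init_mean = init_mean, init_var = init_var)
}

# deterministic RT prediction at log-parameters theta; NULL on recognition
# failure (treated as a rejected optimizer step)
t_star_at <- function(theta, data, model, config) {
  lambda <- exp(theta[1])
  if (!is.finite(lambda) || lambda <= 0) return(NULL)
  st <- tryCatch(
    .recognition_filter_cpp(data$signal, config$eta_face, config$eta_house,
                            config$sigma_u, lambda, model == "dynamic",
                            config$init_mean, config$init_var,
                            1e-8, 500L, 1e-8),
    error = function(e) NULL)
  if (is.null(st)) return(NULL)
  .optimal_rt_series_cpp(st[, 1L], st[, 4L], exp(theta[2]), exp(theta[3]))
}

fd_jacobian <- function(theta, data, model, config) {
  h <- config$fd_step
  J <- matrix(NA_real_, length(data$signal), 3L)
  for (j in 1:3) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    fp <- t_star_at(tp, data, model, config)
    fm <- t_star_at(tm, data, model, config)
    if (is.null(fp) || is.null(fm)) return(NULL)
    J[, j] <- (fp - fm) / (2 * h)
  }
  J
}

#' Penalised log-joint of the response model
#'
#' Runs the nested recognition and reaction-time prediction at the supplied
#' log-parameters and returns the weighted Gaussian log-likelihood of the
#' observed reaction times (noise precision fixed at `phi`, default the
#' prior mean) plus the Gaussian log-prior density, together with its
#' gradient and a Gauss-Newton curvature, both by central finite
#' differences.
#'
#' @param log_params numeric length-3:
#'   `(log lambda, log beta_err, log beta_sens)`.
#' @param data list or data.frame with `signal`, `rt` and `weight` for one
#'   cue stream.
#' @param model `"dynamic"` or `"static"`.
#' @param priors a [prior_spec()].
#' @param config an [inversion_config()].
#' @param phi noise precision at which the likelihood is evaluated.
#' @return list with `value`, `gradient` (length 3) and `curvature` (3 x 3,
#'   negative of the Gauss-Newton Hessian approximation); `value` is `-Inf`
#'   when recognition fails at the supplied parameters.
#' @export
response_objective <- function(log_params, data, model = priors$model,
                               priors = prior_spec(model),
                               config = inversion_config(),
                               phi = priors$a0 / priors$b0) {
  P0 <- diag(1 / priors$var, 3L)
  dtheta <- log_params - priors$mean
  lp_prior <- -0.5 * sum(log(2 * pi * priors$var)) -
    0.5 * sum(dtheta^2 / priors$var)
  n <- length(data$signal)
  if (n == 0L) {
    return(list(value = lp_prior, gradient = -P0 %*% dtheta,
                curvature = -P0))
  }
  ts <- t_star_at(log_params, data, model, config)
  if (is.null(ts)) {
    return(list(value = -Inf, gradient = rep(NA_real_, 3L),
                curvature = matrix(NA_real_, 3L, 3L)))
  }
  w <- data$weight
  r <- data$rt - ts
  value <- rt_loglik(data$rt, ts, phi, w) + lp_prior
  J <- fd_jacobian(log_params, data, model, config)
  if (is.null(J)) {
    return(list(value = value, gradient = rep(NA_real_, 3L),
                curvature = matrix(NA_real_, 3L, 3L)))
  }
  gradient <- phi * crossprod(J, w * r) - P0 %*% dtheta
  curvature <- -(phi * crossprod(J, w * J) + P0)
  list(value = as.numeric(value), gradient = as.numeric(gradient),
       curvature = curvature)
}

# variational free energy of the response model given the current
# posterior factors q(theta) = N(m, S), q(phi) = Gamma(a, b)
response_free_energy <- function(m, S, a, b, r, J, w, priors) {
  n <- length(r)
  d <- 3L
  P0 <- diag(1 / priors$var, d)
  JtWJ <- crossprod(J, w * J)
  E1 <- sum(w * r^2) + sum(JtWJ * S)
  e_phi <- a / b
  e_lnphi <- digamma(a) - log(b)
  dtheta <- m - priors$mean
  0.5 * sum(log(w)) - (n / 2) * log(2 * pi) +
    (n / 2) * e_lnphi - (e_phi / 2) * E1 -
    0.5 * sum(log(priors$var)) -
    0.5 * (sum(dtheta^2 / priors$var) + sum(diag(P0 %*% S))) +
    0.5 * determinant(S, logarithm = TRUE)$modulus + d / 2 +
    priors$a0 * log(priors$b0) - lgamma(priors$a0) +
    (priors$a0 - 1) * e_lnphi - priors$b0 * e_phi +
    a - log(b) + lgamma(a) + (1 - a) * digamma(a)
}

invert_one_start <- function(start, data, model, priors, config) {
  w <- data$weight
  n <- length(data$signal)
  P0 <- diag(1 / priors$var, 3L)
  a <- priors$a0 + n / 2

  eval_state <- function(m, e_phi) {
    ts <- t_star_at(m, data, model, config)
    if (is.null(ts)) return(NULL)
    J <- fd_jacobian(m, data, model, config)
    if (is.null(J)) return(NULL)
    r <- data$rt - ts
    H <- e_phi * crossprod(J, w * J) + P0
    S <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
    if (is.null(S)) return(NULL)
    b <- priors$b0 + 0.5 * (sum(w * r^2) + sum(crossprod(J, w * J) * S))
    FE <- response_free_energy(m, S, a, b, r, J, w, priors)
    list(m = m, S = S, a = a, b = b, r = r, J = J, t_star = ts, F = FE)
  }

  # phase 1 (precision annealing): fix the noise precision at its prior
  # mean and run regularised Gauss-Newton on the penalised least-squares
  # objective; this keeps the likelihood informative while the residuals
  # are still large (otherwise the conjugate phi update immediately
  # attributes the lack of fit to noise and the parameters never move)
  e_phi0 <- priors$a0 / priors$b0
  q_of <- function(m, r) {
    -0.5 * e_phi0 * sum(w * r^2) -
      0.5 * sum((m - priors$mean)^2 / priors$var)
  }
  m_cur <- start
  ts <- t_star_at(m_cur, data, model, config)
  if (is.null(ts)) return(NULL)
  r_cur <- data$rt - ts
  q_cur <- q_of(m_cur, r_cur)
  damp <- 1e-3
  for (it in seq_len(16L)) {
    J <- fd_jacobian(m_cur, data, model, config)
    if (is.null(J)) break
    g <- e_phi0 * crossprod(J, w * r_cur) - P0 %*% (m_cur - priors$mean)
    H <- e_phi0 * crossprod(J, w * J) + P0
    moved <- FALSE
    for (try in 1:8) {
      dm <- tryCatch(solve(H + damp * diag(diag(H) + 1e-8, 3L), g),
                     error = function(e) NULL)
      if (!is.null(dm)) {
        m_new <- m_cur + as.numeric(dm)
        ts_new <- t_star_at(m_new, data, model, config)
        if (!is.null(ts_new)) {
          r_new <- data$rt - ts_new
          q_new <- q_of(m_new, r_new)
          if (is.finite(q_new) && q_new > q_cur) {
            small <- q_new - q_cur < 1e-6 * (1 + abs(q_cur))
            m_cur <- m_new; r_cur <- r_new
            moved <- !small
            damp <- max(damp * 0.3, 1e-8)
            q_cur <- q_new
            break
          }
        }
      }
      damp <- damp * 10
    }
    if (!moved) break
  }

  # phase 2: full variational loop from the annealed mode
  st <- eval_state(m_cur, e_phi0)
  if (is.null(st)) return(NULL)
  st <- eval_state(m_cur, st$a / st$b)
  if (is.null(st)) return(NULL)

  damp <- 1e-3
  F_trace <- st$F
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    e_phi <- st$a / st$b
    g <- e_phi * crossprod(st$J, w * st$r) - P0 %*% (st$m - priors$mean)
    H <- e_phi * crossprod(st$J, w * st$J) + P0
    accepted <- FALSE
    for (try in 1:8) {
      Hd <- H + damp * diag(diag(H) + 1e-8, 3L)
      dm <- tryCatch(solve(Hd, g), error = function(e) NULL)
      if (!is.null(dm)) {
        cand <- eval_state(st$m + as.numeric(dm), e_phi)
        if (!is.null(cand) && is.finite(cand$F) && cand$F >= st$F - 1e-9) {
          delta <- cand$F - st$F
          st <- cand
          F_trace <- c(F_trace, st$F)
          damp <- max(damp * 0.3, 1e-8)
          accepted <- TRUE
          if (abs(delta) < config$tol) converged <- TRUE
          break
        }
      }
      damp <- damp * 10
    }
    if (!accepted || converged) {
      converged <- converged || !accepted && it > 1L
      break
    }
  }
  st$F_trace <- F_trace
  st$converged <- converged
  st
}

#' VB-Laplace inversion of the response model
#'
#' Estimates the posterior over the log-parameters
#' `(log lambda, log beta_err, log beta_sens)` and the noise precision
#' `phi` from one cue stream of reaction times. The scheme alternates
#' regularised Gauss-Newton ascent on the log-parameters (Laplace
#' covariance from the curvature at the mode, Levenberg-style damping,
#' steps accepted only if the free energy does not decrease) with the
#' conjugate Gamma update of `phi` from the weighted residuals, until the
#' free-energy change falls below tolerance. Multi-start restarts jittered
#' around the prior mean guard against local optima; the best free energy
#' wins (ties broken by the smallest deviation from the prior mean).
#'
#' @param data list or data.frame with `signal`, `rt` and `weight`
#'   (weights default to 1 if absent) for a single cue stream; at least 10
#'   usable trials.
#' @param model `"dynamic"` or `"static"` perceptual model.
#' @param priors a [prior_spec()] (defaults to the model's standard
#'   priors).
#' @param config an [inversion_config()].
#' @return an object of class `bdt_fit`: posterior mean `theta_mean` and
#'   covariance `theta_cov` over log-parameters, Gamma posterior
#'   (`phi_shape`, `phi_rate`), `free_energy`, free-energy trace,
#'   convergence flag, fitted `t_star`, residuals, and echoes of priors,
#'   config and model.
#' @export
invert_response_model <- function(data, model = c("dynamic", "static"),
                                  priors = NULL,
                                  config = inversion_config()) {
  model <- match.arg(model)
  if (is.null(priors)) priors <- prior_spec(model)
  data <- as.list(data)
  if (is.null(data$weight)) data$weight <- rep(1, length(data$signal))
  stopifnot(length(data$signal) == length(data$rt),
            length(data$weight) == length(data$rt))
  if (length(data$rt) < 10L) stop("need at least 10 usable trials")

  # Deterministic starts: a grid over log-lambda (the perceptual-parameter
  # landscape can be multimodal), each paired with a data-driven start for
  # the loss trade-off.  Starting beta at the prior mean can leave every
  # predicted reaction time clipped at zero (a flat plateau with no
  # gradient), so log beta_err is chosen to put the predicted times in the
  # range of the observed ones: with beta_sens = 1, t* = log(|dmu|/beta_err)
  # gives beta_err = median|dmu| * exp(-median positive RT).  Any further
  # starts are seeded jitter around these.
  lam_offsets <- c(0, -2, -1, 1, 2)
  n_det <- min(config$n_starts, length(lam_offsets))
  y_pos <- data$rt[data$rt > 0]
  t_ref <- if (length(y_pos)) stats::median(y_pos) else 0.5
  starts <- matrix(rep(priors$mean, config$n_starts), ncol = 3L,
                   byrow = TRUE)
  for (s in seq_len(n_det)) {
    ll <- priors$mean[1] + lam_offsets[s]
    starts[s, 1L] <- ll
    st0 <- tryCatch(
      .recognition_filter_cpp(data$signal, config$eta_face,
                              config$eta_house, config$sigma_u, exp(ll),
                              model == "dynamic", config$init_mean,
                              config$init_var, 1e-8, 500L, 1e-8),
      error = function(e) NULL)
    if (!is.null(st0)) {
      dmu <- stats::median(abs(st0[, "mu_x"] - st0[, "xi"]))
      starts[s, 2L] <- min(max(log(max(dmu, 1e-3)) - t_ref, -6), 2)
      starts[s, 3L] <- 0
    }
  }
  if (config$n_starts > n_det) {
    old <- get_rng_state()
    set.seed(config$seed)
    jit <- matrix(stats::rnorm(3L * (config$n_starts - n_det), 0,
                               config$jitter_sd),
                  ncol = 3L)
    restore_rng_state(old)
    extra <- seq.int(n_det + 1L, config$n_starts)
    starts[extra, ] <- starts[rep(1L, length(extra)), , drop = FALSE] + jit
  }

  best <- NULL
  for (s in seq_len(config$n_starts)) {
    fit <- invert_one_start(starts[s, ], data, model, priors, config)
    if (is.null(fit)) next
    if (is.null(best) || fit$F > best$F + 1e-9 ||
        (abs(fit$F - best$F) <= 1e-9 &&
         sum((fit$m - priors$mean)^2) < sum((best$m - priors$mean)^2))) {
      best <- fit
    }
  }
  if (is.null(best)) stop("inversion failed for all restarts")

  structure(list(theta_mean = stats::setNames(as.numeric(best$m),
                                              c("log_lambda", "log_beta_err",
                                                "log_beta_sens")),
                 theta_cov = best$S,
                 phi_shape = best$a, phi_rate = best$b,
                 phi_mean = best$a / best$b,
                 free_energy = as.numeric(best$F),
                 free_energy_trace = as.numeric(best$F_trace),
                 converged = isTRUE(best$converged),
                 t_star = best$t_star,
                 residuals = best$r,
                 model = model, priors = priors, config = config,
                 n_trials = length(data$rt)),
            class = "bdt_fit")
}

#' @export
print.bdt_fit <- function(x, ...) {
  cat("Response-model inversion (", x$model, " perceptual model)\n", sep = "")
  cat("  trials:", x$n_trials,
      " converged:", x$converged,
      " free energy:", format(x$free_energy, digits = 6), "\n")
  est <- cbind(mean = x$theta_mean, sd = sqrt(diag(x$theta_cov)))
  print(round(est, 4))
  cat("  E[phi] =", format(x$phi_mean, digits = 4), "\n")
  invisible(x)
}

#' Reconstructed belief trajectory with parameter uncertainty
#'
#' Re-runs recognition at the posterior mode of the perceptual parameter
#' and propagates the experimenter's posterior uncertainty about
#' `log lambda` to the per-trial sufficient statistics by first-order
#' sensitivity (delta method).
#'
#' @param fit a `bdt_fit`.
#' @param data the data used for the fit (needs `signal`).
#' @param h finite-difference step on `log lambda` for the sensitivity.
#' @return a data.frame: `trial`, `mu_x`, `mu_a`, `s2_a`, `xi`, and the
#'   parameter-uncertainty variances `var_mu_x`, `var_mu_a`, `var_xi`.
#' @export
representation_posterior <- function(fit, data, h = 1e-3) {
  config <- fit$config
  run <- function(ll) {
    .recognition_filter_cpp(data$signal, config$eta_face, config$eta_house,
                            config$sigma_u, exp(ll),
                            fit$model == "dynamic",
                            config$init_mean, config$init_var,
                            1e-8, 500L, 1e-8)
  }
  ll <- fit$theta_mean[["log_lambda"]]
  st <- run(ll)
  sens <- (run(ll + h) - run(ll - h)) / (2 * h)
  v <- fit$theta_cov[1L, 1L]
  data.frame(trial = seq_len(nrow(st)),
             mu_x = st[, "mu_x"], mu_a = st[, "mu_a"],
             s2_a = st[, "s2_a"], xi = st[, "xi"],
             var_mu_x = sens[, "mu_x"]^2 * v,
             var_mu_a = sens[, "mu_a"]^2 * v,
             var_xi = sens[, "xi"]^2 * v)
}

#' Posterior predictive reaction times
#'
#' Predicted reaction times at the posterior mode, with predictive
#' intervals combining observation noise (at the posterior mean precision)
#' and log-parameter uncertainty propagated through the finite-difference
#' Jacobian.
#'
#' @param fit a `bdt_fit`.
#' @param data the fitted data (`signal`, `rt`, optional `weight`).
#' @param level interval coverage level (default 0.99).
#' @return a data.frame with `t_star`, `rt`, `lower`, `upper`, `residual`;
#'   attributes `r_squared` and `residual_var`.
#' @export
posterior_predictive <- function(fit, data, level = 0.99) {
  data <- as.list(data)
  if (is.null(data$weight)) data$weight <- rep(1, length(data$signal))
  config <- fit$config
  ts <- t_star_at(fit$theta_mean, data, fit$model, config)
  J <- fd_jacobian(fit$theta_mean, data, fit$model, config)
  pred_var <- 1 / (fit$phi_mean * data$weight) +
    rowSums((J %*% fit$theta_cov) * J)
  z <- stats::qnorm(1 - (1 - level) / 2)
  res <- data$rt - ts
  out <- data.frame(t_star = ts, rt = data$rt,
                    lower = ts - z * sqrt(pred_var),
                    upper = ts + z * sqrt(pred_var),
                    residual = res)
  ss_tot <- sum((data$rt - mean(data$rt))^2)
  attr(out, "r_squared") <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
  attr(out, "residual_var") <- sum(data$weight * res^2) / sum(data$weight)
  out
}
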