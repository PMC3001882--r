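# shared fixtures: small synthetic sessions and grid-quadrature oracles

# exact posterior moments and log-evidence over the association for a short
# stimulus sequence, by dense grid quadrature (independent of the package's
# recognition code)
grid_posterior <- function(u, prior_mean, prior_var, eta_face, eta_house,
                           sigma_u, step = 0.002, lim = 15) {
  a <- seq(-lim, lim, by = step)
  lik <- rep(1, length(a))
  for (uk in u) {
    lik <- lik * (stats::dnorm(uk, eta_house, sigma_u) * stats::plogis(a) +
                    stats::dnorm(uk, eta_face, sigma_u) * (1 - stats::plogis(a)))
  }
  w <- stats::dnorm(a, prior_mean, sqrt(prior_var)) * lik
  z <- sum(w) * step
  mu <- sum(a * w) / sum(w)
  list(mean = mu,
       var = sum((a - mu)^2 * w) / sum(w),
       log_evidence = log(z))
}

# a standard single-cue session used across tests: blocked schedule,
# high-discriminability stimuli (ratio 8)
fixture_session <- function(seed = 42L, n_trials = 100L, sigma_u = 0.25) {
  cfg <- schedule_config(n_trials = n_trials, n_cues = 1L, seed = seed)
  env <- perceptual_params("dynamic", lambda = 1, sigma_u = sigma_u)
  simulate_session(cfg, env)
}

# simulate a synthetic subject: recognition under `model` at theta_true,
# optimal RTs, Gaussian noise at the requested SNR
fixture_subject <- function(theta_true, snr_db, seed, model = "dynamic",
                            n_trials = 100L, sigma_u = 0.5) {
  blr <- if (n_trials < 28L) c(n_trials, n_trials) else c(28L, 40L)
  cfg <- schedule_config(n_trials = n_trials, block_len_range = blr,
                         n_cues = 1L, seed = seed)
  s <- simulate_session(cfg, perceptual_params("dynamic", lambda = 1,
                                               sigma_u = sigma_u))
  obs <- perceptual_params(model, lambda = exp(theta_true[1]),
                           sigma_u = sigma_u)
  trace <- run_recognition(s, obs)
  rp <- response_params(beta_err = exp(theta_true[2]),
                        beta_sens = exp(theta_true[3]))
  t_star <- predicted_rt_series(trace, rp)
  phi <- snr_to_noise(t_star, snr_db)
  y <- simulate_rts(t_star, phi, seed = seed + 1L)
  list(data = list(signal = s$signal, rt = y, weight = rep(1, n_trials)),
       session = s, trace = trace, t_star = t_star, phi = phi,
       theta_true = theta_true, sigma_u = sigma_u)
}

inv_cfg <- function(seed = 1L, sigma_u = 0.5, ...) {
  inversion_config(seed = seed, sigma_u = sigma_u, ...)
}
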