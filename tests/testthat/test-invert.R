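test_that("the response objective and its derivatives are consistent", {
  sub <- fixture_subject(c(0.4, -1, 0.3), 20, seed = 31)
  cfg <- inv_cfg(seed = 2)
  pr <- prior_spec("dynamic")
  th <- c(0.2, -0.8, 0.1)
  ob <- response_objective(th, sub$data, "dynamic", pr, cfg)
  h <- 1e-5
  gfd <- vapply(1:3, function(j) {
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (response_objective(tp, sub$data, "dynamic", pr, cfg)$value -
       response_objective(tm, sub$data, "dynamic", pr, cfg)$value) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ob$gradient - gfd) / (abs(gfd) + 1e-8)), 1e-4)

  # zero-data limit: the objective is the log-prior density
  ob0 <- response_objective(th, list(signal = numeric(0), rt = numeric(0),
                                     weight = numeric(0)),
                            "dynamic", pr, cfg)
  expect_equal(ob0$value,
               sum(stats::dnorm(th, pr$mean, sqrt(pr$var), log = TRUE)))

  # a near-zero weight screens a trial from the objective: the same RT
  # perturbation moves the objective ~1e8 times less than at full weight
  perturb <- function(weight) {
    d1 <- sub$data
    d1$weight[7] <- weight
    v1 <- response_objective(th, d1, "dynamic", pr, cfg)$value
    d2 <- d1
    d2$rt[7] <- d2$rt[7] + 5
    abs(response_objective(th, d2, "dynamic", pr, cfg)$value - v1)
  }
  expect_lt(perturb(1e-8) / perturb(1), 1e-7)
})

test_that("near-noiseless reaction times pin down the parameters", {
  th <- c(0.4, -1, 0.3)
  sub <- fixture_subject(th, 120, seed = 33)
  fit <- invert_response_model(sub$data, "dynamic",
                               config = inv_cfg(seed = 4))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$theta_mean - th)), 0.05)
  # recorded free-energy sequence is non-decreasing
  expect_true(all(diff(fit$free_energy_trace) >= -1e-9))
  # posterior predictive reproduces the observations
  pp <- posterior_predictive(fit, sub$data)
  expect_lt(max(abs(pp$t_star - sub$data$rt)), 1e-4)
  expect_error(invert_response_model(list(signal = 1:5, rt = 1:5 / 10,
                                          weight = rep(1, 5)), "dynamic"),
               "10 usable trials")
})

test_that("the free energy lower-bounds importance-sampled log evidence", {
  sub <- fixture_subject(c(0.2, -0.5, 0.2), 10, seed = 41, n_trials = 12)
  pr <- prior_spec("dynamic", mean = c(0, 0, 0), var = c(1, 1, 1),
                   phi_mean = 4, phi_var = 4)
  cfg <- inv_cfg(seed = 3)
  fit <- invert_response_model(sub$data, "dynamic", priors = pr,
                               config = cfg)
  set.seed(9)
  n_draws <- 5e4
  th <- matrix(stats::rnorm(3 * n_draws), ncol = 3)
  phi <- stats::rgamma(n_draws, shape = 4, rate = 1)
  ll <- vapply(seq_len(n_draws), function(i) {
    ts <- decidetime:::t_star_at(th[i, ], sub$data, "dynamic", cfg)
    if (is.null(ts)) return(-Inf)
    rt_loglik(sub$data$rt, ts, phi[i], sub$data$weight)
  }, numeric(1))
  mx <- max(ll)
  w <- exp(ll - mx)
  log_z <- mx + log(mean(w))
  se_log <- stats::sd(w) / (mean(w) * sqrt(n_draws))
  expect_lte(fit$free_energy, log_z + 3 * se_log)
})

test_that("perceptual and response parameters are identifiable at 20 dB", {
  sub <- fixture_subject(c(0.3, -1, 0.2), 20, seed = 21)
  fit <- invert_response_model(sub$data, "dynamic",
                               config = inv_cfg(seed = 2))
  cors <- stats::cov2cor(fit$theta_cov)
  expect_lt(abs(cors[1, 2]), 0.9)
  expect_lt(abs(cors[1, 3]), 0.9)
})

test_that("belief trajectories are recovered with calibrated uncertainty", {
  sub <- fixture_subject(c(0.3, -1, 0.2), 0, seed = 22)
  fit <- invert_response_model(sub$data, "dynamic",
                               config = inv_cfg(seed = 2))
  rp <- representation_posterior(fit, sub$data)
  # accurate reconstruction of the generating observer's beliefs at 0 dB
  expect_gt(stats::cor(rp$mu_a, sub$trace$mu_a), 0.9)

  # delta-method variance within a factor 2 of Monte-Carlo propagation
  set.seed(5)
  draws <- stats::rnorm(400, fit$theta_mean[1], sqrt(fit$theta_cov[1, 1]))
  mc <- vapply(draws, function(ll) {
    run_recognition(sub$data$signal,
                    perceptual_params("dynamic", lambda = exp(ll)))$mu_a
  }, numeric(length(sub$data$signal)))
  mc_var <- apply(mc, 1, stats::var)
  keep <- mc_var > stats::quantile(mc_var, 0.5)
  ratio <- rp$var_mu_a[keep] / mc_var[keep]
  expect_gt(stats::median(ratio), 0.5)
  expect_lt(stats::median(ratio), 2)

  # zero parameter uncertainty propagates to zero trajectory variance
  fit0 <- fit
  fit0$theta_cov[1, 1] <- 0
  rp0 <- representation_posterior(fit0, sub$data)
  expect_equal(max(rp0$var_mu_a), 0)
})

test_that("predictive fit is honest about observation noise", {
  sub <- fixture_subject(c(0.3, -1, 0.2), 0, seed = 22)
  fit <- invert_response_model(sub$data, "dynamic",
                               config = inv_cfg(seed = 2))
  pp <- posterior_predictive(fit, sub$data)
  # at SNR 0 dB the fit looks poor even though recovery is good
  expect_lt(attr(pp, "r_squared"), 0.7)
  expect_lt(max(abs(fit$theta_mean - c(0.3, -1, 0.2))), 0.75)

  # predictive intervals are calibrated when the noise level is generated
  # at the prior-mean precision
  covs <- c()
  r <- 0
  while (length(covs) < 4 && r < 40) {
    r <- r + 1
    set.seed(600 + r)
    th <- stats::runif(3, -1, 1)
    cfg <- schedule_config(n_trials = 100, n_cues = 1, seed = 700 + r)
    s <- simulate_session(cfg, perceptual_params("dynamic", lambda = 1))
    tr <- run_recognition(s, perceptual_params("dynamic",
                                               lambda = exp(th[1])))
    ts <- predicted_rt_series(tr, response_params(exp(th[2]), exp(th[3])))
    if (stats::sd(ts) < 0.1) next
    y <- simulate_rts(ts, 1e4, seed = 800 + r)
    d <- list(signal = s$signal, rt = y, weight = rep(1, 100))
    f <- invert_response_model(d, "dynamic", config = inv_cfg(seed = r))
    ppc <- posterior_predictive(f, d)
    covs <- c(covs, mean(y >= ppc$lower & y <= ppc$upper))
  }
  expect_gte(mean(covs), 0.95)
})
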