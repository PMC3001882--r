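test_that("sigmoid is symmetric, increasing, and saturates without overflow", {
  expect_equal(sigmoid(0), 0.5)
  a <- seq(-10, 10, by = 0.37)
  expect_equal(sigmoid(a) + sigmoid(-a), rep(1, length(a)))
  expect_true(all(diff(sigmoid(a)) > 0))
  expect_gte(sigmoid(30), 1 - 1e-9)
  expect_true(is.finite(sigmoid(800)) && is.finite(sigmoid(-800)))
})

test_that("prediction step propagates the prior correctly", {
  ps <- perceptual_params("static", lambda = 1)
  pr <- predict_trial(NULL, ps)
  expect_equal(pr$prior_mean, 0)
  expect_equal(pr$prior_var, 1)
  expect_equal(pr$xi, 0.5)

  pd <- perceptual_params("dynamic", lambda = 2)
  pr2 <- predict_trial(list(mu_a = 0.3, s2_a = 0.2), pd)
  expect_equal(pr2$prior_var, 0.7)
  expect_equal(pr2$prior_mean, 0.3)

  # no diffusion in the infinite-precision limit
  pd0 <- perceptual_params("dynamic", lambda = 1e15)
  pr3 <- predict_trial(list(mu_a = -0.4, s2_a = 0.5), pd0)
  expect_equal(pr3$prior_var, 0.5, tolerance = 1e-12)

  expect_error(predict_trial(list(mu_a = 0, s2_a = -1), pd),
               "non-positive")
})

test_that("a fully symmetric trial leaves beliefs untouched", {
  pp <- perceptual_params("static", lambda = 1)
  pred <- predict_trial(NULL, pp)
  r <- update_trial(pred, 0, pp)   # u equidistant from the two means
  expect_equal(r$mu_x, 0.5, tolerance = 1e-8)
  expect_equal(r$mu_a, 0, tolerance = 1e-8)
})

test_that("recognition matches dense-grid exact Bayes on 2-trial problems", {
  # high-discriminability instances (ratio 8), subject parameters around
  # the dynamic prior mean
  set.seed(42)
  err_mean <- err_var <- numeric(100)
  for (i in 1:100) {
    lam <- exp(stats::runif(1, -0.7, 0.7))
    a_true <- stats::rnorm(1, 0, sqrt(1 / lam))
    x <- stats::rbinom(2, 1, stats::plogis(a_true))
    u <- stats::rnorm(2, ifelse(x == 1, 1, -1), 0.25)
    pp <- perceptual_params("static", lambda = lam, sigma_u = 0.25)
    tr <- run_recognition(u, pp)
    g <- grid_posterior(u, 0, 1 / lam, -1, 1, 0.25)
    err_mean[i] <- abs(tr$mu_a[2] - g$mean)
    err_var[i] <- abs(tr$s2_a[2] / g$var - 1)
  }
  expect_lt(max(err_mean), 0.05)
  expect_lt(max(err_var), 0.2)
})

test_that("perceptual free energy lower-bounds the grid log-evidence", {
  set.seed(7)
  for (i in 1:100) {
    m <- stats::runif(1, -2, 2)
    v <- stats::runif(1, 0.1, 5)
    su <- stats::runif(1, 0.3, 1.5)
    u <- stats::rnorm(1, sample(c(-1, 1), 1), su)
    pp <- perceptual_params("static", lambda = 1 / v, sigma_u = su)
    pred <- list(prior_mean = m, prior_var = v,
                 xi = sigmoid(m / sqrt(1 + pi * v / 8)))
    r <- update_trial(pred, u, pp)
    fe <- perceptual_free_energy(r, pred, u, pp)
    g <- grid_posterior(u, m, v, -1, 1, su)
    expect_lte(fe, g$log_evidence + 1e-6)
    # converged representation improves on the initialisation (prior)
    fe0 <- perceptual_free_energy(list(mu_x = pred$xi, mu_a = m, s2_a = v),
                                  pred, u, pp)
    expect_gte(fe, fe0 - 1e-9)
  }
})

test_that("degenerate-likelihood limit isolates the category term", {
  su <- 1e-4
  pp <- perceptual_params("static", lambda = 1, sigma_u = su)
  pred <- predict_trial(NULL, pp)
  r <- update_trial(pred, 1, pp)    # u exactly at the house mean
  fe <- perceptual_free_energy(r, pred, 1, pp)
  sensory_const <- stats::dnorm(1, 1, su, log = TRUE)
  # the remainder is the category surprise log(xi) = log(0.5) plus the
  # (small) association divergence
  expect_equal(fe - sensory_const, log(0.5), tolerance = 0.1)
  expect_equal(r$mu_x, 1, tolerance = 1e-8)
})

test_that("recognition traces behave as the models predict", {
  s <- fixture_session(seed = 5)
  # static model: posterior variance strictly decreasing
  trs <- run_recognition(s, perceptual_params("static", lambda = 1,
                                              sigma_u = 0.25))
  expect_true(all(diff(trs$s2_a) < 0))

  # dynamic model tracks the blocked association
  trd <- run_recognition(s, perceptual_params("dynamic", lambda = 1,
                                              sigma_u = 0.25))
  expect_gt(stats::cor(trd$mu_a, s$a_true), 0.8)
  # perfect category recognition at high discriminability
  expect_lt(max(abs(trd$mu_x - s$category)), 1e-3)
  # posterior variance floored by the volatility: never below a positive
  # bound in a volatile world
  expect_gt(min(trd$s2_a), 0.01)

  # uninformative stimuli leave the association prior untouched
  tre <- run_recognition(s$signal,
                         perceptual_params("dynamic", lambda = 1,
                                           sigma_u = 1e6))
  expect_lt(max(abs(tre$mu_a)), 1e-3)

  # free energy finite everywhere, trace aligned with trials
  expect_true(all(is.finite(trd$free_energy)))
  expect_equal(nrow(trd), nrow(s))
  expect_error(run_recognition(numeric(0), perceptual_params()), "empty")
})

test_that("the R reference engine and the compiled filter agree", {
  s <- fixture_session(seed = 12, n_trials = 60)
  for (mod in c("static", "dynamic")) {
    pp <- perceptual_params(mod, lambda = 1.7, sigma_u = 0.25)
    a <- run_recognition(s, pp)
    b <- run_recognition(s, pp, engine = "R")
    expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-10)
  }
})

test_that("the static model is the limiting case of the dynamic model", {
  s <- fixture_session(seed = 9, n_trials = 80)
  lam_s <- 1.5
  trs <- run_recognition(s, perceptual_params("static", lambda = lam_s,
                                              sigma_u = 0.25))
  trd <- run_recognition(s, perceptual_params("dynamic", lambda = 1e9,
                                              sigma_u = 0.25),
                         init_mean = 0, init_var = 1 / lam_s)
  expect_equal(trd$mu_a, trs$mu_a, tolerance = 1e-3)
  expect_equal(trd$s2_a, trs$s2_a, tolerance = 1e-3)
})

test_that("recognition is causal", {
  s <- fixture_session(seed = 14, n_trials = 50)
  pp <- perceptual_params("dynamic", lambda = 1, sigma_u = 0.25)
  full <- run_recognition(s$signal, pp)
  edited <- s$signal
  edited[41:50] <- -edited[41:50]
  part <- run_recognition(edited, pp)
  expect_equal(full$mu_a[1:40], part$mu_a[1:40])
  expect_equal(full$mu_x[1:40], part$mu_x[1:40])
})

test_that("the effective learning rate mirrors assumed volatility", {
  s <- fixture_session(seed = 5)
  lams <- exp(seq(-2, 2, by = 1))
  lr <- vapply(lams, function(l) {
    tr <- run_recognition(s, perceptual_params("dynamic", lambda = l,
                                               sigma_u = 0.25))
    stats::median(abs(effective_learning_rate(tr)), na.rm = TRUE)
  }, numeric(1))
  # stable world (high precision) -> low learning rate, monotone
  expect_true(all(diff(lr) < 0))

  # zero prediction error: guarded, returns NA
  trace0 <- data.frame(mu_a = c(0, 0), mu_x = c(0.5, 0.5), xi = c(0.5, 0.5))
  expect_true(all(is.na(effective_learning_rate(trace0))))

  # constant-association session: stable learning rate at convergence
  cfgc <- schedule_config(n_trials = 150, block_len_range = c(150, 150),
                          association_levels = 0.6,
                          include_random_blocks = FALSE, n_cues = 1,
                          seed = 11)
  sc <- simulate_session(cfgc, perceptual_params("dynamic", lambda = 2,
                                                 sigma_u = 0.25))
  trc <- run_recognition(sc, perceptual_params("dynamic", lambda = 2,
                                               sigma_u = 0.25))
  late <- utils::tail(effective_learning_rate(trc), 20)
  expect_lt(stats::sd(late, na.rm = TRUE) / abs(mean(late, na.rm = TRUE)),
            0.2)
})

test_that("internal Gauss-Hermite rule matches an independent implementation", {
  skip_if_not_installed("pracma")
  gh <- decidetime:::gauss_hermite(20)
  ref <- pracma::gaussHermite(20)
  expect_equal(gh$nodes, ref$x, tolerance = 1e-12)
  expect_equal(gh$weights, ref$w, tolerance = 1e-12)
})
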