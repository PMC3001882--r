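#' Monte-Carlo validation configuration
#'
#' One simulation series: synthetic subjects whose true perceptual model is
#' static (series "A") or dynamic (series "B"), with true log-parameters
#' drawn uniformly within `sampling_range` (natural log) of the prior
#' means, sessions of `n_trials` trials on a blocked schedule, and
#' reaction-time noise set by a target signal-to-noise ratio.
#'
#' @param series `"A"` (static-generated) or `"B"` (dynamic-generated).
#' @param n_sims simulated subjects per cell (default 50; reduced-rep runs
#'   use 20).
#' @param n_trials trials per session (default 100).
#' @param snr_db_levels SNR levels in dB (default 40, 20, 0).
#' @param sampling_range half-width of the uniform log-parameter sampling
#'   interval around the prior means.
#' @param min_rt_sd minimum standard deviation (seconds) of a simulated
#'   subject's deterministic reaction-time series; parameter draws whose
#'   behaviour is flatter than this are rejected and counted (empirical
#'   reaction-time series vary on the 0.1 s scale and flatter sessions
#'   carry no trial-to-trial learning signal).
#' @param seed master seed.
#' @param inversion an [inversion_config()] used for all inversions.
#' @return a list of class `mc_config`.
#' @export
mc_config <- function(series = c("A", "B"), n_sims = 50L, n_trials = 100L,
                      snr_db_levels = c(40, 20, 0), sampling_range = 2,
                      min_rt_sd = 0.1, seed = 1L,
                      inversion = inversion_config()) {
  series <- match.arg(series)
  stopifnot(n_sims >= 1L, all(is.finite(snr_db_levels)), min_rt_sd >= 0)
  list(series = series, n_sims = as.integer(n_sims),
       n_trials = as.integer(n_trials),
       snr_db_levels = snr_db_levels,
       sampling_range = sampling_range,
       min_rt_sd = min_rt_sd,
       seed = as.integer(seed),
       inversion = inversion)
}

#' Noise precision for a target signal-to-noise ratio
#'
#' SNR (dB) is defined as `10 log10(var(t_star) / noise variance)`; given a
#' deterministic reaction-time series, returns the noise precision `phi`
#' achieving the target.
#'
#' @param t_star deterministic reaction-time series (non-degenerate).
#' @param snr_db target SNR in decibels.
#' @return noise precision `phi` (1/s^2).
#' @export
snr_to_noise <- function(t_star, snr_db) {
  v <- stats::var(t_star)
  if (!is.finite(v) || v <= 0) stop("zero-variance reaction-time signal")
  noise_var <- v / 10^(snr_db / 10)
  1 / noise_var
}

# simulate one synthetic subject: schedule, recognition under the true
# model, optimal RTs, noise at the target SNR
simulate_mc_subject <- function(true_model, theta_true, n_trials, snr_db,
                                seed, inversion) {
  cfg <- schedule_config(n_trials = n_trials, n_cues = 1L, seed = seed)
  env <- perceptual_params("dynamic", lambda = 1,
                           eta_face = inversion$eta_face,
                           eta_house = inversion$eta_house,
                           sigma_u = inversion$sigma_u)
  seq_df <- simulate_session(cfg, env, use_schedule = TRUE)
  obs <- perceptual_params(true_model, lambda = exp(theta_true[1]),
                           eta_face = inversion$eta_face,
                           eta_house = inversion$eta_house,
                           sigma_u = inversion$sigma_u)
  trace <- run_recognition(seq_df, obs,
                           init_mean = inversion$init_mean,
                           init_var = inversion$init_var)
  rp <- response_params(beta_err = exp(theta_true[2]),
                        beta_sens = exp(theta_true[3]), phi = 1)
  ts <- predicted_rt_series(trace, rp)
  phi <- snr_to_noise(ts, snr_db)
  y <- simulate_rts(ts, phi, seed = seed + 1L)
  list(data = list(signal = seq_df$signal, rt = y,
                   weight = rep(1, length(y))),
       trace = trace, t_star = ts, phi = phi)
}

#' Run one Monte-Carlo cell (series x SNR)
#'
#' For each simulated subject: draw true log-parameters, generate a
#' session, run the true observer, add reaction-time noise at the target
#' SNR, invert the response model under both perceptual models, and record
#' the free-energy difference in favour of the true model together with
#' log-space sum-of-squared-error recovery scores under the true model.
#' Subjects whose deterministic reaction-time series is degenerate (no
#' variance, so the SNR is undefined) are excluded and counted.
#'
#' @param cfg an [mc_config()].
#' @param snr_db the SNR level for this cell.
#' @return a data.frame of class `mc_cell` with one row per completed
#'   simulation: true and estimated log-parameters, `f_static`, `f_dynamic`,
#'   `delta_f` (true-model minus other-model free energy), `winner`
#'   (logical: true model preferred), `sse_percept`, `sse_response`;
#'   attribute `n_excluded`.
#' @export
run_mc_cell <- function(cfg, snr_db) {
  true_model <- if (cfg$series == "A") "static" else "dynamic"
  pm <- prior_spec(true_model)$mean
  seeds <- child_seeds(cfg$seed + round(100 * snr_db), 2L * cfg$n_sims)
  rows <- list()
  n_excluded <- 0L
  for (i in seq_len(cfg$n_sims)) {
    s_par <- seeds[2L * i - 1L]
    s_sim <- seeds[2L * i]
    # rejection-sample a behaviourally plausible subject: deterministic
    # reaction times must vary by at least min_rt_sd (sd), as empirical RT
    # series do; rejected draws are counted
    sub <- NULL
    for (attempt in 0:49) {
      old <- get_rng_state()
      set.seed(s_par + attempt)
      theta_true <- pm + stats::runif(3L, -cfg$sampling_range,
                                      cfg$sampling_range)
      restore_rng_state(old)
      cand <- tryCatch(
        simulate_mc_subject(true_model, theta_true, cfg$n_trials, snr_db,
                            s_sim + attempt, cfg$inversion),
        error = function(e) NULL)
      if (!is.null(cand) && stats::sd(cand$t_star) >= cfg$min_rt_sd) {
        sub <- cand
        break
      }
      n_excluded <- n_excluded + 1L
    }
    if (is.null(sub)) next
    inv_cfg <- cfg$inversion
    inv_cfg$seed <- s_sim
    fits <- lapply(c(static = "static", dynamic = "dynamic"), function(mod) {
      tryCatch(invert_response_model(sub$data, mod, config = inv_cfg),
               error = function(e) NULL)
    })
    if (is.null(fits$static) || is.null(fits$dynamic)) {
      n_excluded <- n_excluded + 1L
      next
    }
    f_true <- if (true_model == "static") fits$static$free_energy else
      fits$dynamic$free_energy
    f_other <- if (true_model == "static") fits$dynamic$free_energy else
      fits$static$free_energy
    est <- fits[[true_model]]$theta_mean
    rows[[length(rows) + 1L]] <- data.frame(
      sim = i, seed = s_sim, snr_db = snr_db, series = cfg$series,
      true_log_lambda = theta_true[1], true_log_beta_err = theta_true[2],
      true_log_beta_sens = theta_true[3],
      est_log_lambda = est[["log_lambda"]],
      est_log_beta_err = est[["log_beta_err"]],
      est_log_beta_sens = est[["log_beta_sens"]],
      f_static = fits$static$free_energy,
      f_dynamic = fits$dynamic$free_energy,
      delta_f = f_true - f_other,
      winner = f_true > f_other,
      sse_percept = (est[["log_lambda"]] - theta_true[1])^2,
      sse_response = (est[["log_beta_err"]] - theta_true[2])^2 +
        (est[["log_beta_sens"]] - theta_true[3])^2)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("mc_cell", "data.frame")
  out
}

#' Log-space sum-of-squared-error recovery score
#'
#' @param estimated,true log-parameter vectors of equal length.
#' @return nonnegative scalar.
#' @export
sse_score <- function(estimated, true) {
  stopifnot(length(estimated) == length(true))
  sum((estimated - true)^2)
}

#' Summarise Monte-Carlo cells into evidence and recovery tables
#'
#' @param cells a list of `mc_cell` results (any series / SNR mix).
#' @return a data.frame with one row per (series, SNR): mean free-energy
#'   difference in favour of the true model, model-selection accuracy, and
#'   mean perceptual / response SSE.
#' @export
summarize_tables <- function(cells) {
  df <- do.call(rbind, lapply(cells, as.data.frame))
  agg <- do.call(rbind, lapply(split(df, list(df$series, df$snr_db),
                                     drop = TRUE), function(g) {
    data.frame(series = g$series[1], snr_db = g$snr_db[1],
               n = nrow(g),
               mean_delta_f = mean(g$delta_f),
               selection_accuracy = mean(g$winner),
               mean_sse_percept = mean(g$sse_percept),
               mean_sse_response = mean(g$sse_response))
  }))
  agg <- agg[order(agg$series, -agg$snr_db), ]
  rownames(agg) <- NULL
  agg
}
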