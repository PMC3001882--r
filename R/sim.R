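#' Schedule configuration for a simulated associative-learning session
#'
#' Describes the blocked cue-outcome association schedule of one session:
#' blocks of trials within which the probability of the outcome category
#' given the cue is constant, alternating between "predictive" levels and
#' chance-level ("random", p = 0.5) blocks, as in probabilistic
#' associative-learning experiments.
#'
#' @param n_trials number of trials per cue stream (positive integer).
#' @param block_len_range integer pair `(min, max)`: block lengths are drawn
#'   uniformly from this range (inclusive).
#' @param association_levels probabilities in (0, 1) used for predictive
#'   blocks; cycled through in order. Default `c(0.9, 0.7)` (strong,
#'   moderate); the random level 0.5 is fixed by definition.
#' @param include_random_blocks if `TRUE` (default) every second block is a
#'   random (p = 0.5) block.
#' @param n_cues number of interleaved cue streams (default 2).
#' @param seed master seed for the session.
#' @return an object of class `schedule_config` (a list).
#' @export
schedule_config <- function(n_trials = 100L,
                            block_len_range = c(28L, 40L),
                            association_levels = c(0.9, 0.7),
                            include_random_blocks = TRUE,
                            n_cues = 2L,
                            seed = 1L) {
  n_trials <- as.integer(n_trials)
  block_len_range <- as.integer(block_len_range)
  stopifnot(length(n_trials) == 1L, n_trials >= 1L,
            length(block_len_range) == 2L,
            block_len_range[1] >= 1L,
            block_len_range[1] <= block_len_range[2],
            all(association_levels > 0 & association_levels < 1),
            n_cues >= 1L)
  if (block_len_range[1] > n_trials) {
    stop("n_trials is smaller than the minimum block length")
  }
  structure(list(n_trials = n_trials,
                 block_len_range = block_len_range,
                 association_levels = association_levels,
                 include_random_blocks = isTRUE(include_random_blocks),
                 n_cues = as.integer(n_cues),
                 seed = as.integer(seed)),
            class = "schedule_config")
}

#' Perceptual model constants
#'
#' The observer's generative model of sensory signals: a two-component
#' Gaussian mixture over the scalar signal (category means `eta_face`,
#' `eta_house`, common spread `sigma_u`) with a Bernoulli category prior
#' linked through the logistic sigmoid to the cue-outcome association. The
#' association is either fixed over trials with a zero-mean Gaussian prior of
#' precision `lambda` (static model) or follows a Gaussian random walk with
#' transition precision `lambda` (dynamic model; 1/lambda is the volatility
#' scale).
#'
#' Defaults give a discrimination ratio `|eta_house - eta_face| / sigma_u`
#' of 4, emulating well-separated natural-image categories.
#'
#' @param model `"dynamic"` or `"static"`.
#' @param lambda positive precision hyperparameter (see above).
#' @param eta_face,eta_house category means of the signal mixture.
#' @param sigma_u positive standard deviation of the signal around its
#'   category mean.
#' @return an object of class `perceptual_params`.
#' @export
perceptual_params <- function(model = c("dynamic", "static"),
                              lambda = 1,
                              eta_face = -1, eta_house = 1,
                              sigma_u = 0.5) {
  model <- match.arg(model)
  stopifnot(lambda > 0, sigma_u > 0, eta_face != eta_house)
  structure(list(model = model, lambda = lambda,
                 eta_face = eta_face, eta_house = eta_house,
                 sigma_u = sigma_u),
            class = "perceptual_params")
}

# child seeds for independent components, derived once from the master seed
child_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

#' Generate a blocked association schedule for one cue stream
#'
#' Draws block lengths uniformly from `cfg$block_len_range` until the stream
#' covers `cfg$n_trials` (the last block is truncated). Predictive levels are
#' cycled through `cfg$association_levels`, alternating the predicted
#' category across successive predictive blocks (p, 1 - p) so that the
#' marginal outcome frequency stays at 1/2 over a balanced schedule; when
#' `include_random_blocks` is set, predictive and random (p = 0.5) blocks
#' alternate.
#'
#' @param cfg a [schedule_config()].
#' @param seed optional seed overriding the config seed.
#' @return a data.frame with columns `length` and `p_outcome`, one row per
#'   block.
#' @export
generate_schedule <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "schedule_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  lengths <- integer(0)
  p <- numeric(0)
  total <- 0L
  i_pred <- 0L          # index over predictive blocks
  is_pred <- TRUE       # predictive blocks first; alternate if random blocks
  len_choices <- seq.int(cfg$block_len_range[1], cfg$block_len_range[2])
  while (total < cfg$n_trials) {
    len <- len_choices[sample.int(length(len_choices), 1L)]
    if (is_pred) {
      lev <- cfg$association_levels[(i_pred %% length(cfg$association_levels)) + 1L]
      # alternate the predicted category across predictive blocks
      if (i_pred %% 2L == 1L) lev <- 1 - lev
      i_pred <- i_pred + 1L
    } else {
      lev <- 0.5
    }
    lengths <- c(lengths, len)
    p <- c(p, lev)
    total <- total + len
    if (cfg$include_random_blocks) is_pred <- !is_pred
  }
  over <- total - cfg$n_trials
  if (over > 0L) lengths[length(lengths)] <- lengths[length(lengths)] - over
  data.frame(length = lengths, p_outcome = p)
}

#' Sample a hidden association path
#'
#' Dynamic model: a Gaussian random walk `a_k = a_{k-1} + e_k`,
#' `e_k ~ N(0, 1/lambda)`, started at 0. Static model: a single draw from
#' the zero-mean Gaussian prior with precision `lambda`, held constant.
#'
#' @param params a [perceptual_params()].
#' @param n number of trials (>= 1).
#' @param seed RNG seed.
#' @return numeric vector of associations on the logit scale.
#' @export
sample_association_path <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "perceptual_params"), n >= 1)
  if (params$lambda <= 0) stop("lambda must be positive")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sd_innov <- sqrt(1 / params$lambda)
  if (params$model == "static") {
    rep(stats::rnorm(1L, 0, sd_innov), n)
  } else {
    cumsum(stats::rnorm(n, 0, sd_innov))
  }
}

#' Sample outcome categories and sensory signals
#'
#' Categories are Bernoulli draws with probability `sigmoid(a_true)` (or a
#' scheduled probability supplied directly via `p_outcome`); signals are
#' Gaussian around the category mean.
#'
#' @param params a [perceptual_params()].
#' @param a_true association path on the logit scale (used when `p_outcome`
#'   is `NULL`).
#' @param p_outcome optional per-trial outcome probabilities in (0, 1),
#'   overriding `a_true`.
#' @param seed RNG seed.
#' @return a list with integer vector `category` (1 = house, 0 = face) and
#'   numeric vector `signal`.
#' @export
sample_outcomes_and_signals <- function(params, a_true = NULL,
                                        p_outcome = NULL, seed = 1L) {
  stopifnot(inherits(params, "perceptual_params"))
  if (is.null(p_outcome)) {
    stopifnot(!is.null(a_true))
    p_outcome <- sigmoid(a_true)
  }
  stopifnot(all(p_outcome > 0 & p_outcome < 1))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  n <- length(p_outcome)
  category <- as.integer(stats::runif(n) < p_outcome)
  mu <- ifelse(category == 1L, params$eta_house, params$eta_face)
  signal <- stats::rnorm(n, mu, params$sigma_u)
  list(category = category, signal = signal)
}

#' Simulate a full associative-learning session
#'
#' Generates `cfg$n_cues` independent cue streams. In schedule mode (the
#' default) each stream follows a blocked association schedule from
#' [generate_schedule()]; in generative-model mode (`use_schedule = FALSE`)
#' the hidden association follows the perceptual model itself
#' ([sample_association_path()]). Streams are interleaved uniformly at
#' random into a single trial order.
#'
#' @param cfg a [schedule_config()].
#' @param params a [perceptual_params()] describing the environment.
#' @param use_schedule use the blocked schedule (`TRUE`, default) or sample
#'   the association from the perceptual model.
#' @return a data.frame of class `trial_sequence` with columns `trial`
#'   (1-based, session order), `cue`, `a_true`, `p_outcome`, `category`,
#'   `signal`, ordered by `trial`.
#' @export
simulate_session <- function(cfg, params = perceptual_params(),
                             use_schedule = TRUE) {
  stopifnot(inherits(cfg, "schedule_config"))
  seeds <- child_seeds(cfg$seed, 3L * cfg$n_cues + 1L)
  streams <- vector("list", cfg$n_cues)
  for (c_i in seq_len(cfg$n_cues)) {
    s_sched <- seeds[3L * (c_i - 1L) + 1L]
    s_path  <- seeds[3L * (c_i - 1L) + 2L]
    s_out   <- seeds[3L * (c_i - 1L) + 3L]
    if (use_schedule) {
      plan <- generate_schedule(cfg, seed = s_sched)
      p_outcome <- rep(plan$p_outcome, plan$length)
      # even-numbered cues predict the opposite category, so that the
      # marginal outcome probability is 1/2 by design
      if (c_i %% 2L == 0L) p_outcome <- 1 - p_outcome
      a_true <- stats::qlogis(p_outcome)
      os <- sample_outcomes_and_signals(params, p_outcome = p_outcome,
                                        seed = s_out)
    } else {
      a_true <- sample_association_path(params, cfg$n_trials, seed = s_path)
      p_outcome <- sigmoid(a_true)
      os <- sample_outcomes_and_signals(params, a_true = a_true, seed = s_out)
    }
    streams[[c_i]] <- data.frame(cue = c_i,
                                 a_true = a_true,
                                 p_outcome = p_outcome,
                                 category = os$category,
                                 signal = os$signal)
  }
  # interleave streams uniformly at random, preserving within-stream order
  old <- get_rng_state()
  set.seed(seeds[3L * cfg$n_cues + 1L])
  labels <- sample(rep.int(seq_len(cfg$n_cues), cfg$n_trials))
  restore_rng_state(old)
  idx_within <- stats::ave(labels, labels, FUN = seq_along)
  rows <- lapply(seq_along(labels), function(i) {
    streams[[labels[i]]][idx_within[i], , drop = FALSE]
  })
  df <- do.call(rbind, rows)
  df <- cbind(trial = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  class(df) <- c("trial_sequence", "data.frame")
  df
}
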