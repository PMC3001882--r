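#' Logistic sigmoid
#'
#' Maps an association on the logit scale to the probability of the
#' positive (house) outcome category. Saturates gracefully at extreme
#' inputs.
#'
#' @param a numeric vector.
#' @return probabilities in (0, 1).
#' @export
sigmoid <- function(a) {
  out <- numeric(length(a))
  pos <- !is.na(a) & a >= 0
  out[pos] <- 1 / (1 + exp(-a[pos]))
  e <- exp(a[!pos])
  out[!pos] <- e / (1 + e)
  out[is.na(a)] <- NA_real_
  out
}

softplus <- function(a) ifelse(a > 30, a + exp(-a), log1p(exp(a)))

# Gauss-Hermite nodes/weights (physicists' convention) by Golub-Welsch:
# eigen-decomposition of the symmetric tridiagonal Jacobi matrix.
gauss_hermite <- function(n = 20L) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- sqrt(pi) * e$vectors[1L, ]^2
  ord <- order(nodes)
  list(nodes = nodes[ord], weights = weights[ord])
}

.gh20 <- NULL
gh_cache <- function() {
  if (is.null(.gh20)) {
    utils::assignInMyNamespace(".gh20", gauss_hermite(20L))
  }
  .gh20
}

# E[softplus(a)] under N(m, v), by 20-node Gauss-Hermite quadrature
e_softplus <- function(m, v) {
  gh <- gh_cache()
  z <- outer(sqrt(2 * v), gh$nodes)              # length(m) x 20
  drop((softplus(m + z) %*% gh$weights) / sqrt(pi))
}

#' One-trial prediction step of the observer
#'
#' Propagates the previous posterior over the association into the prior
#' for the current trial. Dynamic model: the prior mean is carried forward
#' and the prior variance grows by the random-walk innovation variance
#' `1/lambda`. Static model: the accumulated posterior is carried forward
#' unchanged, with the trial-1 prior being `N(0, 1/lambda)`. The
#' pre-stimulus outcome prediction `xi` is the prior over the association
#' pushed through the logistic sigmoid using the MacKay moment
#' approximation `sigmoid(m / sqrt(1 + pi v / 8))`.
#'
#' @param prev previous trial representation (a list with `mu_a`, `s2_a`)
#'   or `NULL` for the first trial.
#' @param params a [perceptual_params()].
#' @param init_mean,init_var initial belief for the dynamic model's first
#'   trial (defaults 0 and 1).
#' @return list with `prior_mean`, `prior_var`, `xi`.
#' @export
predict_trial <- function(prev, params, init_mean = 0, init_var = 1) {
  stopifnot(inherits(params, "perceptual_params"))
  if (is.null(prev)) {
    if (params$model == "static") {
      m <- 0; v <- 1 / params$lambda
    } else {
      m <- init_mean; v <- init_var
    }
  } else {
    m <- prev$mu_a
    v <- if (params$model == "static") prev$s2_a else prev$s2_a + 1 / params$lambda
  }
  if (v <= 0) stop("non-positive prior variance")
  list(prior_mean = m, prior_var = v,
       xi = sigmoid(m / sqrt(1 + pi * v / 8)))
}

# first two moments of the tilted association density
#   p~(a) ~ N(a; m, v) exp(mu_x a - softplus(a)),
# by Gauss-Hermite quadrature recentred (and widened) at the mode of the
# strictly log-concave tilt
tilted_moments <- function(mu_x, m, v) {
  a <- m
  for (j in 1:50) {
    s <- sigmoid(a)
    g <- mu_x - s - (a - m) / v
    h <- -s * (1 - s) - 1 / v
    step <- max(min(-g / h, 5), -5)
    a <- a + step
    if (abs(step) < 1e-12) break
  }
  sl <- sigmoid(a)
  s2_lap <- 1 / (1 / v + sl * (1 - sl))
  sig <- sqrt(2 * s2_lap)
  gh <- gh_cache()
  z <- a + sqrt(2) * sig * gh$nodes
  lf <- mu_x * z - softplus(z) - (z - m)^2 / (2 * v) + (z - a)^2 / (2 * sig^2)
  w <- gh$weights * exp(lf - max(lf))
  mu <- sum(w * z) / sum(w)
  list(mean = mu, var = sum(w * (z - mu)^2) / sum(w))
}

#' One-trial recognition update
#'
#' Mean-field update of the observer's beliefs after seeing the sensory
#' signal `u`: coordinate iteration alternates the closed-form Bernoulli
#' update (log-odds = sensory log-likelihood ratio + posterior mean
#' association) with a Gaussian factor matched to the first two moments of
#' the tilted association posterior (mode-recentred Gauss-Hermite
#' quadrature of the strictly log-concave tilt). Iterates to a fixed point
#' (tolerance 1e-8, max 500 sweeps).
#'
#' @param pred output of [predict_trial()].
#' @param u scalar sensory signal (finite).
#' @param params a [perceptual_params()].
#' @param tol,max_iter fixed-point tolerance and iteration cap.
#' @return list with `mu_x`, `mu_a`, `s2_a`, `xi`, `prior_mean`,
#'   `prior_var`.
#' @export
update_trial <- function(pred, u, params, tol = 1e-8, max_iter = 500L) {
  stopifnot(is.finite(u))
  m <- pred$prior_mean; v <- pred$prior_var
  llr <- ((u - params$eta_face)^2 - (u - params$eta_house)^2) /
    (2 * params$sigma_u^2)
  # the coordinate fixed point satisfies mu_a = t(mu_a) with
  # t(a) = tilted_mean(sigmoid(llr + a)); t is increasing and maps
  # [t at mu_x=0, t at mu_x=1] into itself, so roots of g = t - id are
  # bracketed; multiple roots (bistable trials) are resolved by the trial
  # free energy
  tmap <- function(a) tilted_moments(sigmoid(llr + a), m, v)$mean
  # fast path: damped fixed-point iteration from the prior mean
  fast_root <- local({
    a <- m; d_prev <- Inf; relax <- 1; res <- NULL
    for (it in 1:50) {
      tm <- tmap(a)
      d <- abs(tm - a)
      if (d < tol) { res <- a; break }
      if (d >= 0.99 * d_prev && relax > 0.2) relax <- relax / 2
      d_prev <- d
      a <- a + relax * (tm - a)
    }
    res
  })
  roots <- if (!is.null(fast_root)) {
    fast_root
  } else if ({lo <- tilted_moments(0, m, v)$mean
              hi <- tilted_moments(1, m, v)$mean
              hi - lo < tol}) {
    (lo + hi) / 2
  } else {
    grid <- seq(lo, hi, length.out = 33L)
    gv <- vapply(grid, function(a) tmap(a) - a, numeric(1))
    found <- grid[abs(gv) < 1e-9 * (1 + abs(grid))]
    for (i in seq_len(length(grid) - 1L)) {
      if (gv[i] > 0 && gv[i + 1L] < 0) {
        a_lo <- grid[i]; a_hi <- grid[i + 1L]
        for (j in seq_len(60L)) {
          mid <- (a_lo + a_hi) / 2
          if (tmap(mid) - mid > 0) a_lo <- mid else a_hi <- mid
          if (a_hi - a_lo < tol) break
        }
        found <- c(found, (a_lo + a_hi) / 2)
      }
    }
    if (!length(found)) stop("recognition update failed to converge")
    found
  }
  cand <- lapply(roots, function(a) {
    mu_x <- sigmoid(llr + a)
    tm <- tilted_moments(mu_x, m, v)
    list(mu_x = mu_x, mu_a = tm$mean, s2_a = max(tm$var, 1e-8),
         xi = pred$xi, prior_mean = m, prior_var = v)
  })
  if (length(cand) > 1L) {
    fe <- vapply(cand, function(r) perceptual_free_energy(r, pred, u, params),
                 numeric(1))
    cand <- cand[which.max(fe)]
  }
  cand[[1L]]
}

#' Per-trial perceptual free energy
#'
#' The variational lower bound on the log-evidence of the sensory signal
#' `u` for one trial, evaluated at the representation `repr` under the
#' prior implied by `pred`: expected log-joint (sensory mixture term,
#' Bernoulli/sigmoid category term with the softplus expectation computed
#' by Gauss-Hermite quadrature, Gaussian association term) plus the
#' entropies of the Bernoulli and Gaussian factors.
#'
#' @param repr a representation (list with `mu_x`, `mu_a`, `s2_a`), e.g.
#'   from [update_trial()]; vectors are accepted for vectorised evaluation.
#' @param pred prior for the trial (list with `prior_mean`, `prior_var`).
#' @param u sensory signal(s).
#' @param params a [perceptual_params()].
#' @return free energy value(s), in nats.
#' @export
perceptual_free_energy <- function(repr, pred, u, params) {
  mu_x <- repr$mu_x; mu_a <- repr$mu_a; s2 <- repr$s2_a
  m <- pred$prior_mean; v <- pred$prior_var
  ll1 <- stats::dnorm(u, params$eta_house, params$sigma_u, log = TRUE)
  ll0 <- stats::dnorm(u, params$eta_face, params$sigma_u, log = TRUE)
  hb <- -ifelse(mu_x > 0, mu_x * log(mu_x), 0) -
    ifelse(mu_x < 1, (1 - mu_x) * log(1 - mu_x), 0)
  mu_x * ll1 + (1 - mu_x) * ll0 +
    mu_x * mu_a - e_softplus(mu_a, s2) -
    0.5 * log(2 * pi * v) - (s2 + (mu_a - m)^2) / (2 * v) +
    hb + 0.5 * log(2 * pi * exp(1) * s2)
}

#' Run recognition over a session
#'
#' Sequential application of [predict_trial()] and [update_trial()] over a
#' single cue stream, returning the full trajectory of the observer's
#' sufficient statistics and the per-trial perceptual free energy. The
#' default engine is a compiled filter; `engine = "R"` runs the pure-R
#' reference implementation (identical results).
#'
#' @param x a `trial_sequence` containing a single cue stream (or any
#'   data.frame with a `signal` column), or a numeric vector of signals.
#' @param params a [perceptual_params()] describing the observer.
#' @param init_mean,init_var dynamic-model initial belief (defaults 0, 1).
#' @param engine `"cpp"` (default) or `"R"`.
#' @return a data.frame of class `recognition_trace` with columns `trial`,
#'   `mu_x`, `mu_a`, `s2_a`, `xi`, `free_energy`.
#' @export
run_recognition <- function(x, params, init_mean = 0, init_var = 1,
                            engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (is.data.frame(x)) {
    if ("cue" %in% names(x) && length(unique(x$cue)) > 1L) {
      stop("run_recognition expects a single cue stream; subset by cue first")
    }
    u <- x$signal
  } else {
    u <- as.numeric(x)
  }
  if (length(u) == 0L) stop("empty sequence")
  if (engine == "cpp") {
    st <- .recognition_filter_cpp(u, params$eta_face, params$eta_house,
                                  params$sigma_u, params$lambda,
                                  params$model == "dynamic",
                                  init_mean, init_var, 1e-8, 500L, 1e-8)
    st <- as.data.frame(st)
  } else {
    prev <- NULL
    rows <- vector("list", length(u))
    for (k in seq_along(u)) {
      pred <- predict_trial(prev, params, init_mean, init_var)
      rep_k <- update_trial(pred, u[k], params)
      rows[[k]] <- rep_k
      prev <- rep_k
    }
    st <- do.call(rbind.data.frame, rows)
  }
  fe <- perceptual_free_energy(st, list(prior_mean = st$prior_mean,
                                        prior_var = st$prior_var),
                               u, params)
  out <- data.frame(trial = seq_along(u), mu_x = st$mu_x, mu_a = st$mu_a,
                    s2_a = st$s2_a, xi = st$xi, free_energy = fe)
  class(out) <- c("recognition_trace", "data.frame")
  out
}

#' Empirical per-trial learning rate
#'
#' The ratio of the change in the association belief to the outcome
#' prediction error (`mu_x - xi`) — the effective Rescorla-Wagner learning
#' rate implied by the recognition trace. Trials whose prediction error is
#' numerically zero return `NA`.
#'
#' @param trace a `recognition_trace` (dynamic model).
#' @param eps prediction errors below this magnitude yield `NA`.
#' @return numeric vector, one value per trial (first trial uses the
#'   initial belief 0 as reference).
#' @export
effective_learning_rate <- function(trace, eps = 1e-10) {
  d_mu <- diff(c(0, trace$mu_a))
  pe <- trace$mu_x - trace$xi
  ifelse(abs(pe) < eps, NA_real_, d_mu / pe)
}
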