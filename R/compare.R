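#' Log Bayes factor from free energies
#'
#' Difference of free-energy bounds on log model evidence; values of 3 or
#' more are conventionally taken as strong evidence.
#'
#' @param f_a,f_b finite free energies of models A and B.
#' @return `f_a - f_b`, with attribute `strength` (`"strong"` when
#'   `|lbf| >= 3`, `"weak"` otherwise).
#' @export
log_bayes_factor <- function(f_a, f_b) {
  stopifnot(is.finite(f_a), is.finite(f_b))
  lbf <- f_a - f_b
  attr(lbf, "strength") <- ifelse(abs(lbf) >= 3, "strong", "weak")
  lbf
}

#' Random-effects group-level Bayesian model selection
#'
#' Variational posterior over model frequencies in the population: each
#' subject is assumed to have drawn one of the candidate models, and model
#' frequencies get a Dirichlet prior (`alpha0`, default 1 per model). The
#' fixed-point scheme alternates subject-wise posterior model assignments
#' with the Dirichlet update until convergence. Exceedance probabilities
#' use the Beta closed form for two models and seeded Monte-Carlo sampling
#' otherwise. Per-subject evidences from several cue streams should be
#' summed per subject beforehand (see `sum_cues` of [evidence_table()]).
#'
#' @param evidence numeric matrix of free energies, rows = subjects,
#'   columns = models (column names carried into the result).
#' @param alpha0 Dirichlet prior counts (scalar or one per model).
#' @param n_draws Monte-Carlo draws for exceedance with > 2 models.
#' @param seed seed for Monte-Carlo exceedance sampling.
#' @param tol,max_iter fixed-point convergence controls.
#' @return an object of class `bms_result`: `alpha` (posterior Dirichlet),
#'   `expected_frequencies`, `exceedance_probabilities`, and the posterior
#'   model assignments `g` (subjects x models).
#' @export
group_bms <- function(evidence, alpha0 = 1, n_draws = 1e6L, seed = 1L,
                      tol = 1e-8, max_iter = 1000L) {
  evidence <- as.matrix(evidence)
  stopifnot(nrow(evidence) >= 1L, ncol(evidence) >= 2L,
            all(is.finite(evidence)))
  K <- ncol(evidence)
  if (length(alpha0) == 1L) alpha0 <- rep(alpha0, K)
  stopifnot(all(alpha0 > 0))
  alpha <- alpha0
  g <- matrix(1 / K, nrow(evidence), K)
  for (it in seq_len(max_iter)) {
    lu <- sweep(evidence, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1L, max)
    g <- exp(lu) / rowSums(exp(lu))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  xp <- exceedance_probability(alpha, n_draws = n_draws, seed = seed)
  structure(list(alpha = stats::setNames(alpha, colnames(evidence)),
                 expected_frequencies =
                   stats::setNames(alpha / sum(alpha), colnames(evidence)),
                 exceedance_probabilities =
                   stats::setNames(xp, colnames(evidence)),
                 g = g, alpha0 = alpha0),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Group-level random-effects model selection\n")
  print(round(rbind(alpha = x$alpha,
                    `E[freq]` = x$expected_frequencies,
                    exceedance = x$exceedance_probabilities), 4))
  invisible(x)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Probability that each model's population frequency exceeds all others,
#' under `Dirichlet(alpha)`. The two-model case uses the regularised
#' incomplete beta closed form; larger families use seeded Monte-Carlo.
#'
#' @param alpha positive Dirichlet parameters.
#' @param n_draws Monte-Carlo draws (families of > 2 models).
#' @param seed RNG seed for the Monte-Carlo case.
#' @return probabilities summing to 1.
#' @export
exceedance_probability <- function(alpha, n_draws = 1e6L, seed = 1L) {
  stopifnot(all(alpha > 0))
  K <- length(alpha)
  if (K == 2L) {
    p1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    return(c(p1, 1 - p1))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  draws <- matrix(stats::rgamma(n_draws * K, shape = rep(alpha, each = n_draws)),
                  ncol = K)
  win <- max.col(draws)
  tabulate(win, nbins = K) / n_draws
}

#' Assemble an evidence table from per-subject, per-cue fits
#'
#' @param free_energies a data.frame with columns `subject`, `model`,
#'   `free_energy` and optionally `cue`.
#' @param sum_cues sum evidences over cues within subject (default `TRUE`,
#'   the standard choice); if `FALSE`, each (subject, cue) pair becomes a
#'   pseudo-subject row.
#' @return numeric matrix, rows = subjects, columns = models.
#' @export
evidence_table <- function(free_energies, sum_cues = TRUE) {
  stopifnot(all(c("subject", "model", "free_energy") %in%
                  names(free_energies)))
  df <- free_energies
  if (!sum_cues && "cue" %in% names(df)) {
    df$subject <- paste(df$subject, df$cue, sep = ":")
  }
  agg <- stats::aggregate(free_energy ~ subject + model, data = df, FUN = sum)
  tab <- stats::xtabs(free_energy ~ subject + model, data = agg)
  mat <- matrix(as.numeric(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  mat
}
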