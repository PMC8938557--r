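#' MCMC sampler configuration
#'
#' Iteration accounting follows the standard estimation protocol: per chain,
#' `n_iterations` total, the first `burn_in` discarded, every `thin`-th of
#' the remainder retained, so retained draws per chain equal
#' `(n_iterations - burn_in) / thin`. Two presets are provided: `"paper"`
#' mode (3 chains x 16,000 iterations, 6,000 burn-in, thin 5; 6,000 retained
#' draws in total) and a lighter `"fast"` mode (3 x 4,000, 1,000 burn-in,
#' thin 2) for simulation studies and tests.
#'
#' @param mode "paper" or "fast"; ignored when the explicit arguments are
#'   supplied.
#' @param n_chains,n_iterations,burn_in,thin Explicit overrides.
#' @return An object of class `mcmc_config`.
#' @examples
#' mcmc_config("paper")
#' @export
mcmc_config <- function(mode = c("fast", "paper"),
                        n_chains = NULL, n_iterations = NULL,
                        burn_in = NULL, thin = NULL) {
  mode <- match.arg(mode)
  preset <- if (mode == "paper")
    list(n_chains = 3L, n_iterations = 16000L, burn_in = 6000L, thin = 5L)
  else
    list(n_chains = 3L, n_iterations = 4000L, burn_in = 1000L, thin = 2L)
  cfg <- list(
    n_chains = as.integer(n_chains %||% preset$n_chains),
    n_iterations = as.integer(n_iterations %||% preset$n_iterations),
    burn_in = as.integer(burn_in %||% preset$burn_in),
    thin = as.integer(thin %||% preset$thin),
    mode = mode)
  if (cfg$burn_in >= cfg$n_iterations)
    stop("`burn_in` must be smaller than `n_iterations`")
  if (cfg$thin < 1L || cfg$n_chains < 1L)
    stop("`thin` and `n_chains` must be >= 1")
  class(cfg) <- "mcmc_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uniform hyperprior supports for the hierarchical model
#'
#' Defaults: `mu_alpha ~ U(0,1)`, `sigma_alpha ~ U(0,1)`,
#' `mu_beta ~ U(0,10)`, `sigma_beta ~ U(0,5)`. Subject-level normals are
#' truncated to `[0, 1]` for the learning rate and `[0, beta_max]` for
#' choice consistency, with `beta_max` the upper support of `mu_beta`.
#'
#' @param mu_alpha,sigma_alpha,mu_beta,sigma_beta Length-2 `c(lower, upper)`
#'   supports.
#' @return An object of class `hierarchical_priors`.
#' @export
hierarchical_priors <- function(mu_alpha = c(0, 1), sigma_alpha = c(0, 1),
                                mu_beta = c(0, 10), sigma_beta = c(0, 5)) {
  pr <- list(mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
             mu_beta = mu_beta, sigma_beta = sigma_beta)
  for (nm in names(pr)) {
    b <- pr[[nm]]
    if (length(b) != 2L || b[1] >= b[2])
      stop(sprintf("prior support for %s must be c(lower, upper)", nm))
  }
  class(pr) <- "hierarchical_priors"
  pr
}

# split a tidy trial table into per-subject choice/reward integer vectors
trials_to_dataset <- function(trials) {
  stopifnot(all(c("subject_id", "trial", "chosen_deck", "reward") %in%
                  names(trials)))
  ids <- unique(trials$subject_id)
  choices <- list(); rewards <- list()
  for (id in ids) {
    tt <- trials[trials$subject_id == id, ]
    tt <- tt[order(tt$trial), ]
    choices[[length(choices) + 1L]] <-
      ifelse(tt$chosen_deck == "A", 1L, 2L)
    rewards[[length(rewards) + 1L]] <- as.integer(tt$reward)
  }
  list(subject_ids = ids, choices = choices, rewards = rewards)
}

#' Joint log-likelihood of the delta-rule/softmax model
#'
#' Sum over subjects and trials of the log choice probability, with each
#' subject's deck expectations propagated by the delta rule from `q0` along
#' that subject's own realized choices and rewards.
#'
#' @param trials Tidy trial table (columns `subject_id`, `trial`,
#'   `chosen_deck`, `reward`).
#' @param alpha,beta Numeric vectors, one learning rate / choice consistency
#'   per subject, in the order of `unique(trials$subject_id)`.
#' @param q0 Initial expectation for both decks.
#' @return Scalar log-likelihood.
#' @export
rl_loglik <- function(trials, alpha, beta, q0 = 0.5) {
  ds <- trials_to_dataset(trials)
  S <- length(ds$choices)
  if (length(alpha) != S || length(beta) != S)
    stop("need one (alpha, beta) per subject")
  if (any(alpha < 0 | alpha > 1))
    stop("learning rate `alpha` must lie in [0, 1]")
  if (any(beta < 0))
    stop("choice consistency `beta` must be non-negative")
  cpp_loglik(ds$choices, ds$rewards, alpha, beta, q0)
}

#' Fit the hierarchical Bayesian reinforcement-learning model
#'
#' Estimates per-subject learning rates and choice consistencies together
#' with group-level means and standard deviations from trial-by-trial
#' choices, by adaptive random-walk Metropolis-within-Gibbs MCMC. Subject
#' parameters are modelled as group-level normals truncated to the parameter
#' supports; hyperpriors are uniform (see [hierarchical_priors()]). Each
#' group x prime-condition dataset is intended to be fit independently.
#'
#' @param trials Tidy trial table for one dataset (one group x condition):
#'   columns `subject_id`, `trial`, `chosen_deck` ("A"/"B"), `reward` (0/1).
#' @param priors A [hierarchical_priors()].
#' @param config An [mcmc_config()].
#' @param q0 Initial deck expectation (fixed, not estimated).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param use_likelihood Set `FALSE` to sample from the prior only
#'   (prior-recovery diagnostics).
#' @return An object of class `rlhb` with components `draws` (array
#'   `chain x draw x parameter`), `parameters`, `subject_ids`, `config`,
#'   `priors`, `q0`, and `rhat` (per-parameter split-chain diagnostic).
#'   A warning (not an error) is raised when any R-hat exceeds 1.1.
#' @seealso [posterior_summary()], [rhat()], [coef.rlhb()]
#' @examples
#' sched <- make_block_schedule(task_config(), seed = 1)
#' tr <- do.call(rbind, lapply(1:3, function(i)
#'   simulate_subject(0.3, 4, sched, seed = i, subject_id = paste0("s", i))$trials))
#' \donttest{
#' fit <- fit_rlhb(tr, config = mcmc_config(n_iterations = 400, burn_in = 100),
#'                 seed = 1)
#' coef(fit)
#' }
#' @export
fit_rlhb <- function(trials, priors = hierarchical_priors(),
                     config = mcmc_config("fast"), q0 = 0.5, seed = NULL,
                     use_likelihood = TRUE) {
  stopifnot(inherits(priors, "hierarchical_priors"),
            inherits(config, "mcmc_config"))
  ds <- trials_to_dataset(trials)
  S <- length(ds$choices)
  if (S == 0L || any(vapply(ds$choices, length, 0L) == 0L))
    stop("every subject must contribute at least one trial")
  if (!is.null(seed)) set.seed(as.integer(seed))

  alpha_sup <- c(0, 1)
  beta_sup <- c(0, priors$mu_beta[2])
  pnames <- c("mu_alpha", "sigma_alpha", "mu_beta", "sigma_beta",
              paste0("alpha[", ds$subject_ids, "]"),
              paste0("beta[", ds$subject_ids, "]"))
  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  draws <- array(NA_real_,
                 dim = c(config$n_chains, n_keep, length(pnames)),
                 dimnames = list(chain = NULL, draw = NULL,
                                 parameter = pnames))
  for (ch in seq_len(config$n_chains)) {
    m <- cpp_rlhb_chain(ds$choices, ds$rewards, q0,
                        config$n_iterations, config$burn_in, config$thin,
                        priors$mu_alpha, priors$sigma_alpha,
                        priors$mu_beta, priors$sigma_beta,
                        alpha_sup[1], alpha_sup[2],
                        beta_sup[1], beta_sup[2],
                        use_likelihood)
    draws[ch, , ] <- m
  }
  fit <- structure(
    list(draws = draws, parameters = pnames, subject_ids = ds$subject_ids,
         config = config, priors = priors, q0 = q0,
         n_subjects = S,
         n_trials = vapply(ds$choices, length, 0L),
         use_likelihood = use_likelihood),
    class = "rlhb")
  fit$rhat <- rhat(fit)
  bad <- fit$rhat[is.finite(fit$rhat) & fit$rhat > 1.1]
  if (length(bad))
    warning(sprintf(
      "possible non-convergence: %d parameter(s) with split R-hat > 1.1 (max %.3f)",
      length(bad), max(bad)))
  fit
}

#' Posterior summaries of an `rlhb` fit
#'
#' Pools retained draws across chains and reports, per parameter, the
#' posterior mean (the point estimate used downstream), median, standard
#' deviation, and the central 95% interval.
#'
#' @param fit An [fit_rlhb()] object.
#' @return Data frame with one row per parameter.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "rlhb"))
  flat <- apply(fit$draws, 3, c)   # (chain*draw) x parameter
  if (is.null(dim(flat))) flat <- matrix(flat, nrow = 1)
  data.frame(
    parameter = fit$parameters,
    mean = colMeans(flat),
    median = apply(flat, 2, median),
    sd = apply(flat, 2, sd),
    q2.5 = apply(flat, 2, quantile, 0.025),
    q97.5 = apply(flat, 2, quantile, 0.975),
    rhat = as.numeric(fit$rhat),
    row.names = NULL)
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half; R-hat is `sqrt(((n-1)/n * W + B/n) / W)`
#' with `W` the mean within-half variance and `B` the between-half-mean
#' variance scaled by the half length. Values near 1 indicate the chains
#' mix over the same distribution.
#'
#' @param fit An `rlhb` fit (or an array `chain x draw x parameter`).
#' @return Named numeric vector, one R-hat per parameter (`NA` when fewer
#'   than 2 draws per half or zero within-chain variance).
#' @export
rhat <- function(fit) {
  draws <- if (inherits(fit, "rlhb")) fit$draws else fit
  stopifnot(length(dim(draws)) == 3L)
  n_par <- dim(draws)[3]
  out <- vapply(seq_len(n_par), function(p) {
    halves <- list()
    for (ch in seq_len(dim(draws)[1])) {
      x <- draws[ch, , p]
      h <- length(x) %/% 2L
      if (h < 2L) return(NA_real_)
      halves <- c(halves, list(x[seq_len(h)], x[h + seq_len(h)]))
    }
    n <- length(halves[[1]])
    w <- mean(vapply(halves, var, 0))
    b <- n * var(vapply(halves, mean, 0))
    if (!is.finite(w) || w <= 0) return(NA_real_)
    sqrt(((n - 1) / n * w + b / n) / w)
  }, 0)
  names(out) <- dimnames(draws)[[3]]
  out
}

#' Monte Carlo standard error by batch means
#'
#' @param x Numeric vector of (possibly autocorrelated) MCMC draws.
#' @param n_batches Number of batches.
#' @return Estimated standard error of `mean(x)`.
#' @export
mcse <- function(x, n_batches = 30L) {
  n <- length(x)
  b <- n %/% n_batches
  if (b < 2L) return(sd(x) / sqrt(n))
  means <- vapply(seq_len(n_batches),
                  function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  sd(means) / sqrt(n_batches)
}

#' @export
print.rlhb <- function(x, ...) {
  cat("Hierarchical Bayesian delta-rule/softmax fit\n")
  cat(sprintf("  %d subjects, %s trials each\n", x$n_subjects,
              paste(range(x$n_trials), collapse = "-")))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d draws\n",
              x$config$n_chains, x$config$n_iterations, x$config$burn_in,
              x$config$thin, x$config$n_chains * dim(x$draws)[2]))
  hyp <- posterior_summary(x)[1:4, c("parameter", "mean", "q2.5", "q97.5",
                                     "rhat")]
  print(hyp, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.rlhb <- function(object, ...) {
  posterior_summary(object)
}

#' Posterior-mean parameter estimates
#'
#' @param object An `rlhb` fit.
#' @param which "hyper" for the four group-level parameters, "subject" for
#'   the per-subject data frame, "all" for everything.
#' @param ... Unused.
#' @return Named vector ("hyper"/"all") or a data frame ("subject") of
#'   posterior means.
#' @export
coef.rlhb <- function(object, which = c("hyper", "subject", "all"), ...) {
  which <- match.arg(which)
  s <- posterior_summary(object)
  est <- stats::setNames(s$mean, s$parameter)
  if (which == "hyper") return(est[1:4])
  if (which == "all") return(est)
  S <- object$n_subjects
  data.frame(subject_id = object$subject_ids,
             alpha = unname(est[4 + seq_len(S)]),
             beta = unname(est[4 + S + seq_len(S)]))
}

#' Trace plot of the group-level parameters
#'
#' @param x An `rlhb` fit.
#' @param parameters Parameter names to plot (default: the hyperparameters).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rlhb <- function(x, parameters = x$parameters[1:4], ...) {
  old <- par(mfrow = c(length(parameters), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  for (p in parameters) {
    matplot(t(x$draws[, , p]), type = "l", lty = 1, ylab = p,
            xlab = "retained draw", ...)
  }
  invisible(x)
}
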