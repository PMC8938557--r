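test_that("draw accounting honors iteration/burn-in/thin arithmetic", {
  paper <- mcmc_config("paper")
  expect_equal(paper$n_chains * (paper$n_iterations - paper$burn_in) /
                 paper$thin, 6000)
  fast <- mcmc_config("fast")
  expect_equal((fast$n_iterations - fast$burn_in) / fast$thin, 1500)
  expect_error(mcmc_config(burn_in = 5000, n_iterations = 4000), "burn_in")
})

test_that("log-likelihood matches hand propagation and is additive", {
  # beta = 0: indifference
  tr <- data.frame(subject_id = "a", trial = 0:1,
                   chosen_deck = c("A", "B"), reward = c(1, 0))
  expect_equal(rl_loglik(tr, 0.5, 0), 2 * log(0.5), tolerance = 1e-12)

  # 3-trial toy propagated by hand through the delta rule and softmax
  tr3 <- data.frame(subject_id = "a", trial = 0:2,
                    chosen_deck = c("A", "B", "A"), reward = c(1, 0, 1))
  a <- 0.3; b <- 2; q0 <- 0.5
  # t1: qa=qb=0.5 -> P(A)=0.5, chose A, reward 1 -> qa=0.65
  # t2: P(B) = 1 - plogis(b*(0.65-0.5)), chose B, reward 0 -> qb=0.35
  # t3: P(A) = plogis(b*(0.65-0.35))
  by_hand <- log(0.5) + log(1 - plogis(b * 0.15)) + log(plogis(b * 0.3))
  expect_equal(rl_loglik(tr3, a, b), by_hand, tolerance = 1e-12)

  # additivity over subjects and invariance to subject order
  tr2 <- transform(tr3, subject_id = "b")
  both <- rbind(tr3, tr2)
  expect_equal(rl_loglik(both, c(a, a), c(b, b)),
               2 * rl_loglik(tr3, a, b), tolerance = 1e-12)
  swapped <- rbind(tr2, tr3)
  expect_equal(rl_loglik(swapped, c(a, a), c(b, b)),
               rl_loglik(both, c(a, a), c(b, b)))
  expect_error(rl_loglik(tr3, 1.5, 1), "\\[0, 1\\]")
})

test_that("retained draws respect parameter supports and counts", {
  ds <- recovery_dataset(n_subjects = 4, seed = 3)
  fit <- suppressWarnings(
    fit_rlhb(ds$trials,
             config = mcmc_config(n_iterations = 600, burn_in = 200,
                                  thin = 2),
             seed = 5))
  expect_equal(dim(fit$draws), c(3, 200, 4 + 2 * 4))
  al <- fit$draws[, , grep("^alpha", fit$parameters)]
  be <- fit$draws[, , grep("^beta", fit$parameters)]
  expect_true(all(al >= 0 & al <= 1))
  expect_true(all(be >= 0 & be <= 10))
  expect_true(all(fit$draws[, , "mu_alpha"] >= 0 &
                    fit$draws[, , "mu_alpha"] <= 1))
  expect_true(all(fit$draws[, , "sigma_beta"] >= 0 &
                    fit$draws[, , "sigma_beta"] <= 5))
})

test_that("fits are deterministic given a seed", {
  ds <- recovery_dataset(n_subjects = 3, seed = 8)
  cfg <- mcmc_config(n_iterations = 400, burn_in = 100, thin = 3)
  a <- suppressWarnings(fit_rlhb(ds$trials, config = cfg, seed = 21))
  b <- suppressWarnings(fit_rlhb(ds$trials, config = cfg, seed = 21))
  expect_identical(a$draws, b$draws)
})

test_that("posterior summaries reduce draws correctly", {
  fit <- structure(list(
    draws = array(rep(c(0, 1), each = 3), dim = c(3, 2, 1),
                  dimnames = list(NULL, NULL, "x")),
    parameters = "x", rhat = c(x = NA_real_)), class = "rlhb")
  s <- posterior_summary(fit)
  expect_equal(s$mean, 0.5)

  const <- structure(list(
    draws = array(2.5, dim = c(2, 50, 1),
                  dimnames = list(NULL, NULL, "c")),
    parameters = "c", rhat = c(c = NA_real_)), class = "rlhb")
  sc <- posterior_summary(const)
  expect_equal(sc$mean, 2.5)
  expect_equal(sc$q2.5, 2.5)
  expect_equal(sc$q97.5, 2.5)
})

test_that("split R-hat flags divergent chains and passes identical ones", {
  set.seed(31)
  base <- matrix(rnorm(4000), nrow = 2)
  draws <- array(NA_real_, c(2, 2000, 1),
                 dimnames = list(NULL, NULL, "x"))
  draws[1, , 1] <- base[1, ]; draws[2, , 1] <- base[2, ]
  r <- rhat(draws)
  expect_lt(abs(r - 1), 0.05)

  # identical chains: between-chain variance zero, R-hat ~ 1
  same <- draws; same[2, , 1] <- same[1, , 1]
  expect_lt(abs(rhat(same) - 1), 0.05)

  div <- draws; div[2, , 1] <- div[2, , 1] + 10
  expect_gt(rhat(div), 1.1)
})

test_that("prior sampling recovers the uniform hyperprior means", {
  ds <- recovery_dataset(n_subjects = 5, seed = 12)
  short <- ds$trials[ds$trials$trial < 2, ]
  # prior-only sampling is cheap, so run long chains for tight MC error
  fit <- suppressWarnings(
    fit_rlhb(short,
             config = mcmc_config(n_iterations = 20000, burn_in = 2000,
                                  thin = 5),
             seed = 13, use_likelihood = FALSE))
  chain_se <- function(p) {
    ses <- apply(fit$draws[, , p], 1, mcse)
    sqrt(sum(ses^2)) / nrow(fit$draws[, , p])
  }
  ma <- mean(fit$draws[, , "mu_alpha"])
  mb <- mean(fit$draws[, , "mu_beta"])
  expect_lt(abs(ma - 0.5), 3 * chain_se("mu_alpha"))
  expect_lt(abs(mb - 5.0), 3 * chain_se("mu_beta"))
})

test_that("hyperparameters are recovered from simulated subjects", {
  ds <- recovery_dataset(n_subjects = 20, mu_alpha = 0.30,
                         sigma_alpha = 0.10, mu_beta = 4.0,
                         sigma_beta = 1.0, seed = 42)
  fit <- fit_rlhb(ds$trials, config = mcmc_config("fast"), seed = 7)
  est <- coef(fit)
  expect_lt(abs(est[["mu_alpha"]] - 0.30), 0.10)
  expect_lt(abs(est[["mu_beta"]] - 4.0), 1.0)
  subj <- coef(fit, "subject")
  expect_gte(cor(ds$alpha, subj$alpha), 0.6)
})

test_that("posterior means agree with an independent JAGS fit", {
  set.seed(55)
  n_sub <- 4; n_tr <- 150
  true_a <- c(0.2, 0.3, 0.4, 0.35); true_b <- c(3, 4, 5, 4.5)
  cfg <- task_config(n_experimental_trials = n_tr, n_blocks = 2,
                     block_length_range = c(70, 80))
  trials <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
    sc <- make_block_schedule(cfg, seed = 300 + i)
    simulate_subject(true_a[i], true_b[i], sc, seed = 400 + i,
                     subject_id = sprintf("s%d", i))$trials
  }))
  fit <- fit_rlhb(trials, config = mcmc_config("fast"), seed = 17)

  model <- "
  model {
    mu_a ~ dunif(0, 1); sig_a ~ dunif(0.001, 1)
    mu_b ~ dunif(0, 10); sig_b ~ dunif(0.001, 5)
    for (i in 1:S) {
      alpha[i] ~ dnorm(mu_a, 1 / (sig_a * sig_a)) T(0, 1)
      beta[i] ~ dnorm(mu_b, 1 / (sig_b * sig_b)) T(0, 10)
      Q[i, 1, 1] <- 0.5
      Q[i, 1, 2] <- 0.5
      for (t in 1:T) {
        p[i, t] <- 1 / (1 + exp(-beta[i] * (Q[i, t, 1] - Q[i, t, 2])))
        y[i, t] ~ dbern(p[i, t])
        Q[i, t + 1, 1] <- Q[i, t, 1] +
          y[i, t] * alpha[i] * (r[i, t] - Q[i, t, 1])
        Q[i, t + 1, 2] <- Q[i, t, 2] +
          (1 - y[i, t]) * alpha[i] * (r[i, t] - Q[i, t, 2])
      }
    }
  }"
  y <- matrix(NA_real_, n_sub, n_tr); r <- matrix(NA_real_, n_sub, n_tr)
  for (i in seq_len(n_sub)) {
    tt <- trials[trials$subject_id == sprintf("s%d", i), ]
    tt <- tt[order(tt$trial), ]
    y[i, ] <- as.integer(tt$chosen_deck == "A")
    r[i, ] <- tt$reward
  }
  jm <- rjags::jags.model(textConnection(model),
                          data = list(S = n_sub, T = n_tr, y = y, r = r),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 99))
  update(jm, 1500, progress.bar = "none")
  post <- rjags::coda.samples(jm, c("mu_a", "mu_b", "alpha"), 3000,
                              progress.bar = "none")
  jags_means <- colMeans(as.matrix(post))

  est <- coef(fit)
  expect_lt(abs(est[["mu_alpha"]] - jags_means[["mu_a"]]), 0.12)
  expect_lt(abs(est[["mu_beta"]] - jags_means[["mu_b"]]), 1.2)
  subj <- coef(fit, "subject")
  for (i in seq_len(n_sub))
    expect_lt(abs(subj$alpha[i] -
                    jags_means[[sprintf("alpha[%d]", i)]]), 0.12)
})

test_that("empty datasets and invalid priors are rejected", {
  expect_error(fit_rlhb(data.frame(subject_id = character(),
                                   trial = integer(),
                                   chosen_deck = character(),
                                   reward = integer())))
  expect_error(hierarchical_priors(mu_alpha = c(1, 0)), "lower")
})
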