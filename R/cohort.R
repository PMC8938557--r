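#' Configuration of the synthetic study cohort
#'
#' Encodes the study design dimensions (38 patients, 26 controls, three
#' facial-prime conditions) together with the generative settings for every
#' measurement stream: group x condition hyperparameters of the
#' reinforcement-learning model, group x condition ERP template amplitudes,
#' the EEG noise model, PANAS affect shifts, PANSS factor distributions, and
#' a planted correlation matrix linking angry-condition subject-level
#' measures to the five symptom factors via a Gaussian copula.
#'
#' Default group differences are directional: patients are configured with a
#' higher group-mean learning rate, lower choice consistency, attenuated
#' N170, attenuated angry-condition P200, and an attenuated FRN in the
#' emotional conditions; the planted correlations default to the observed
#' significant/marginal angry-condition cells (e.g. FRN x positive -0.436,
#' FRN x cognitive -0.447).
#'
#' @param n_sz,n_ctrl Group sizes.
#' @param conditions Prime-condition labels.
#' @param hyper Nested list `group -> condition -> c(mu_alpha, sigma_alpha,
#'   mu_beta, sigma_beta)`; `NULL` for the defaults described above.
#' @param erp Nested list `group -> condition -> c(n170, p200, frn)`
#'   window-mean template amplitudes in uV; `NULL` for defaults.
#' @param erp_subject_sd Between-subject SDs of the three template
#'   amplitudes, uV.
#' @param eeg List: `srate` (Hz), `noise_sd` (uV), `pink_exponent`,
#'   `blink_rate` (per minute), `enabled`.
#' @param panas Nested list `group -> condition -> c(pos_shift, neg_shift)`
#'   mean post-minus-pre shifts; `NULL` for defaults (controls react to
#'   both emotional primes, patients' response to angry primes is blunted).
#' @param panas_noise_sd Item-level rating noise SD.
#' @param symptom_means,symptom_sds,symptom_items Named parameters of the
#'   five PANSS factors (means/SDs from the reported patient sample; item
#'   counts set the clipping floor, one point per item).
#' @param planted_cor 4 x 5 matrix of planted correlations between the
#'   angry-condition measures (rows: alpha, beta, p200, frn) and the five
#'   factors (columns); must make the joint latent correlation matrix
#'   positive semi-definite.
#' @param task A [task_config()].
#' @param q0 Initial deck expectation used by the simulated agents.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_sz = 38L, n_ctrl = 26L,
                          conditions = c("neutral", "angry", "happy"),
                          hyper = NULL, erp = NULL,
                          erp_subject_sd = c(n170 = 0.8, p200 = 1.2,
                                             frn = 1.0),
                          eeg = list(srate = 1000, noise_sd = 10,
                                     pink_exponent = 0, blink_rate = 0,
                                     enabled = TRUE),
                          panas = NULL, panas_noise_sd = 0.4,
                          symptom_means = c(positive = 8.39,
                                            negative = 12.68,
                                            cognitive = 6.68,
                                            excitement = 5.45,
                                            depressive = 4.95),
                          symptom_sds = c(positive = 3.53, negative = 4.03,
                                          cognitive = 2.52,
                                          excitement = 2.37,
                                          depressive = 1.89),
                          symptom_items = c(positive = 4, negative = 6,
                                            cognitive = 3, excitement = 4,
                                            depressive = 3),
                          planted_cor = NULL,
                          task = task_config(), q0 = 0.5) {
  if (is.null(hyper)) hyper <- list(
    CTRL = list(neutral = c(0.25, 0.10, 5.5, 1.0),
                angry = c(0.35, 0.10, 4.5, 1.0),
                happy = c(0.35, 0.10, 4.5, 1.0)),
    SZ = list(neutral = c(0.45, 0.12, 2.5, 0.8),
              angry = c(0.47, 0.12, 2.4, 0.8),
              happy = c(0.55, 0.12, 1.8, 0.8)))
  if (is.null(erp)) erp <- list(
    CTRL = list(neutral = c(n170 = -5.0, p200 = 4.0, frn = -3.3),
                angry = c(n170 = -5.0, p200 = 6.0, frn = -4.2),
                happy = c(n170 = -5.0, p200 = 6.0, frn = -4.1)),
    SZ = list(neutral = c(n170 = -3.5, p200 = 4.0, frn = -3.1),
              angry = c(n170 = -3.5, p200 = 4.2, frn = -2.0),
              happy = c(n170 = -3.5, p200 = 5.5, frn = -2.2)))
  if (is.null(panas)) panas <- list(
    CTRL = list(neutral = c(0, 0), angry = c(-0.1, 0.8),
                happy = c(0.8, -0.1)),
    SZ = list(neutral = c(0, 0), angry = c(0, 0.1), happy = c(0.5, 0)))
  if (is.null(planted_cor)) {
    planted_cor <- matrix(0, 4, 5,
                          dimnames = list(c("alpha", "beta", "p200", "frn"),
                                          names(symptom_means)))
    planted_cor["alpha", "positive"] <- 0.310
    planted_cor["beta", "positive"] <- -0.334
    planted_cor["p200", "negative"] <- -0.362
    planted_cor["p200", "cognitive"] <- -0.344
    planted_cor["frn", "positive"] <- -0.436
    planted_cor["frn", "cognitive"] <- -0.447
  }
  cfg <- list(n_sz = as.integer(n_sz), n_ctrl = as.integer(n_ctrl),
              conditions = conditions, hyper = hyper, erp = erp,
              erp_subject_sd = erp_subject_sd, eeg = eeg, panas = panas,
              panas_noise_sd = panas_noise_sd,
              symptom_means = symptom_means, symptom_sds = symptom_sds,
              symptom_items = symptom_items, planted_cor = planted_cor,
              task = task, q0 = q0)
  if (cfg$n_sz < 1L || cfg$n_ctrl < 1L) stop("group sizes must be >= 1")
  ev <- eigen(latent_cor_matrix(planted_cor), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("planted correlation matrix makes the joint latent correlation ",
         "matrix non-positive-semi-definite")
  class(cfg) <- "cohort_config"
  cfg
}

# joint correlation matrix of (4 measure latents, 5 factor latents)
latent_cor_matrix <- function(planted_cor) {
  rbind(cbind(diag(4), planted_cor),
        cbind(t(planted_cor), diag(5)))
}

# truncated-normal quantile transform of a uniform u over [lo, hi]
qtruncnorm <- function(u, mu, sig, lo, hi) {
  plo <- pnorm(lo, mu, sig)
  phi <- pnorm(hi, mu, sig)
  qnorm(plo + u * (phi - plo), mu, sig)
}

rtruncnorm <- function(n, mu, sig, lo, hi) {
  qtruncnorm(runif(n), mu, sig, lo, hi)
}

#' PANSS five-factor scores from latent values
#'
#' Maps standard-normal latents to factor scores with the configured means
#' and SDs, clipped at the theoretical minimum of one point per item
#' (positive = P1+P3+P5+G9, negative = N1+N2+N3+N4+N6+G7, cognitive =
#' P2+N5+G11, excitement = P4+P7+G8+G14, depressive = G2+G3+G6).
#'
#' @param z Matrix (subjects x 5) of standard-normal latents, columns in
#'   factor order.
#' @param means,sds,items Named length-5 numeric vectors (see
#'   [cohort_config()] defaults).
#' @return Data frame of factor scores, one row per subject.
#' @export
symptom_scores <- function(z, means = cohort_config()$symptom_means,
                           sds = cohort_config()$symptom_sds,
                           items = cohort_config()$symptom_items) {
  stopifnot(ncol(z) == 5L)
  out <- sapply(seq_len(5L), function(j)
    pmax(means[j] + sds[j] * z[, j], items[j]))
  out <- as.data.frame(matrix(out, nrow = nrow(z)))
  names(out) <- names(means)
  out
}

#' Generate a full synthetic study
#'
#' Draws subject-level model parameters from the configured group x
#' condition truncated normals, simulates every subject's three sessions on
#' fresh block schedules, assigns per-subject ERP template amplitudes,
#' generates PANAS pre/post item ratings, and (for patients) PANSS factor
#' scores whose planted correlations with the angry-condition measures are
#' realized through a Gaussian copula on shared subject-level latents.
#' Continuous EEG is not stored (sessions are long); it is re-synthesized
#' deterministically on demand by [cohort_erp_measures()] from per-session
#' seeds stored in the study object.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the study is a deterministic function of
#'   `(config, seed)`.
#' @return An object of class `synthetic_study`: list with `roster`,
#'   `params` (true subject-level alpha/beta and ERP amplitudes, plus the
#'   per-session EEG seed), `trials`, `panas`, `symptoms` (patients only),
#'   `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  roster <- data.frame(
    subject_id = c(sprintf("SZ%02d", seq_len(config$n_sz)),
                   sprintf("CT%02d", seq_len(config$n_ctrl))),
    group = rep(c("SZ", "CTRL"), c(config$n_sz, config$n_ctrl)))

  # copula latents for patients: (alpha, beta, p200, frn) in the angry
  # condition jointly with the five symptom factors
  R <- latent_cor_matrix(config$planted_cor)
  Lch <- chol(R + diag(1e-10, nrow(R)))
  z_sz <- matrix(rnorm(config$n_sz * nrow(R)), config$n_sz) %*% Lch
  colnames(z_sz) <- c("alpha", "beta", "p200", "frn",
                      names(config$symptom_means))

  params <- list(); trials <- list(); panas <- list()
  for (i in seq_len(nrow(roster))) {
    g <- roster$group[i]
    id <- roster$subject_id[i]
    for (cond in config$conditions) {
      hp <- config$hyper[[g]][[cond]]
      if (g == "SZ" && cond == "angry") {
        ua <- pnorm(z_sz[i, "alpha"]); ub <- pnorm(z_sz[i, "beta"])
        alpha <- qtruncnorm(ua, hp[1], hp[2], 0, 1)
        beta <- qtruncnorm(ub, hp[3], hp[4], 0, 10)
      } else {
        alpha <- rtruncnorm(1, hp[1], hp[2], 0, 1)
        beta <- rtruncnorm(1, hp[3], hp[4], 0, 10)
      }
      amp <- config$erp[[g]][[cond]]
      sds <- config$erp_subject_sd
      if (g == "SZ" && cond == "angry") {
        p200_i <- amp[["p200"]] + sds[["p200"]] * z_sz[i, "p200"]
        # more negative FRN <-> higher latent would flip the sign of the
        # planted correlation; amplitudes are signed, so add directly
        frn_i <- amp[["frn"]] + sds[["frn"]] * z_sz[i, "frn"]
        n170_i <- amp[["n170"]] + sds[["n170"]] * rnorm(1)
      } else {
        n170_i <- amp[["n170"]] + sds[["n170"]] * rnorm(1)
        p200_i <- amp[["p200"]] + sds[["p200"]] * rnorm(1)
        frn_i <- amp[["frn"]] + sds[["frn"]] * rnorm(1)
      }
      sched_seed <- sample.int(.Machine$integer.max, 1)
      sim_seed <- sample.int(.Machine$integer.max, 1)
      eeg_seed <- sample.int(.Machine$integer.max, 1)
      sched <- make_block_schedule(config$task, seed = sched_seed)
      sim <- simulate_subject(alpha, beta, sched, q0 = config$q0,
                              seed = sim_seed, subject_id = id,
                              condition = cond)
      trials[[length(trials) + 1L]] <- sim$trials
      params[[length(params) + 1L]] <- data.frame(
        subject_id = id, group = g, condition = cond,
        alpha = alpha, beta = beta,
        n170 = n170_i, p200 = p200_i, frn = frn_i,
        eeg_seed = eeg_seed)
      sh <- config$panas[[g]][[cond]]
      pre <- pmin(pmax(round(rnorm(20, 2.5, 0.8)), 1), 5)
      shift <- rep(c(sh[1], sh[2]), each = 10)
      post <- pmin(pmax(round(pre + shift +
                                rnorm(20, 0, config$panas_noise_sd)), 1), 5)
      pd <- panas_diff(pre, post, rep(c("positive", "negative"), each = 10))
      panas[[length(panas) + 1L]] <- data.frame(
        subject_id = id, group = g, condition = cond,
        positive_diff = pd$positive_diff,
        negative_diff = pd$negative_diff)
    }
  }
  symptoms <- cbind(
    data.frame(subject_id = roster$subject_id[roster$group == "SZ"]),
    symptom_scores(z_sz[, 5:9, drop = FALSE], config$symptom_means,
                   config$symptom_sds, config$symptom_items))

  structure(list(roster = roster,
                 params = do.call(rbind, params),
                 trials = do.call(rbind, trials),
                 panas = do.call(rbind, panas),
                 symptoms = symptoms,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d SZ + %d CTRL, %d conditions, %d trials/session (seed %d)\n",
    x$config$n_sz, x$config$n_ctrl, length(x$config$conditions),
    x$config$task$n_experimental_trials, x$seed))
  invisible(x)
}

#' Re-synthesize a stored session's continuous EEG
#'
#' @param study A [generate_cohort()] result.
#' @param subject_id,condition Session selector.
#' @return The session's [eeg_continuous()], regenerated deterministically
#'   from the per-session seed and true template amplitudes.
#' @export
cohort_eeg <- function(study, subject_id, condition) {
  stopifnot(inherits(study, "synthetic_study"))
  p <- study$params[study$params$subject_id == subject_id &
                      study$params$condition == condition, ]
  if (nrow(p) != 1L) stop("unknown subject/condition")
  tt <- study$trials[study$trials$subject_id == subject_id &
                       study$trials$condition == condition, ]
  tt <- tt[order(tt$trial), ]
  e <- study$config$eeg
  synth_eeg(tt, erp_templates(n170 = p$n170, p200 = p$p200, frn = p$frn),
            srate = e$srate, noise_sd = e$noise_sd,
            pink_exponent = e$pink_exponent %||% 0,
            blink_rate = e$blink_rate %||% 0, seed = p$eeg_seed)
}

#' Pipeline-measured ERP amplitudes across a cohort
#'
#' Synthesizes each requested session's EEG and runs the full extraction
#' pipeline ([erp_amplitudes()]), returning measured N170, P200 and FRN
#' per subject x condition alongside the generating truth.
#'
#' @param study A [generate_cohort()] result.
#' @param subject_ids Subjects to process (default all).
#' @param conditions Conditions to process (default all).
#' @param filter Apply the bandpass stage (default `TRUE`).
#' @return Data frame: subject_id, group, condition, measured `n170`,
#'   `p200`, `frn`, truth columns `*_true`, and epoch counts.
#' @export
cohort_erp_measures <- function(study,
                                subject_ids = study$roster$subject_id,
                                conditions = study$config$conditions,
                                filter = TRUE) {
  stopifnot(inherits(study, "synthetic_study"))
  rows <- list()
  for (id in subject_ids) {
    for (cond in conditions) {
      p <- study$params[study$params$subject_id == id &
                          study$params$condition == cond, ]
      tt <- study$trials[study$trials$subject_id == id &
                           study$trials$condition == cond, ]
      tt <- tt[order(tt$trial), ]
      eeg <- cohort_eeg(study, id, cond)
      amp <- erp_amplitudes(eeg, tt, filter = filter)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, group = p$group, condition = cond,
        n170 = amp$n170, p200 = amp$p200, frn = amp$frn,
        n170_true = p$n170, p200_true = p$p200, frn_true = p$frn,
        n_unexpected_win = amp$n_unexpected_win,
        n_unexpected_loss = amp$n_unexpected_loss)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
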