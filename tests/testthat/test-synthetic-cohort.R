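# small task so cohort-level properties can be checked over many seeds
tiny_task_config <- function(n_trials = 12)
  task_config(n_experimental_trials = n_trials, n_blocks = 2,
              block_length_range = c(n_trials / 2, n_trials / 2))

test_that("default cohort has the study's design dimensions", {
  cfg <- cohort_config(task = tiny_task_config())
  st <- generate_cohort(cfg, seed = 2)
  expect_equal(nrow(st$roster), 38 + 26)
  expect_equal(sum(st$roster$group == "SZ"), 38)
  expect_equal(sum(st$roster$group == "CTRL"), 26)
  expect_equal(nrow(st$params), 64 * 3)
  # every subject has all three conditions
  tab <- table(st$params$subject_id)
  expect_true(all(tab == 3))
  expect_equal(nrow(st$symptoms), 38)
  # truth stored for recovery: parameters within their supports
  expect_true(all(st$params$alpha >= 0 & st$params$alpha <= 1))
  expect_true(all(st$params$beta >= 0 & st$params$beta <= 10))
})

test_that("cohorts are byte-identical under a repeated seed", {
  cfg <- cohort_config(task = tiny_task_config())
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$trials, c$trials))
})

test_that("planted FRN-symptom correlation is realized on average", {
  cfg <- cohort_config(task = tiny_task_config())
  target <- cfg$planted_cor["frn", "positive"]
  rs <- vapply(1:60, function(s) {
    st <- generate_cohort(cfg, seed = 1000 + s)
    sz <- st$params[st$params$group == "SZ" &
                      st$params$condition == "angry", ]
    m <- merge(sz, st$symptoms, by = "subject_id")
    cor(m$frn, m$positive)
  }, 0)
  expect_lt(abs(mean(rs) - target), 0.15)
})

test_that("null planted correlations stay near zero at n = 38", {
  cfg <- cohort_config(task = tiny_task_config(),
                       planted_cor = matrix(0, 4, 5))
  n_seeds <- 100
  inside <- vapply(seq_len(n_seeds), function(s) {
    st <- generate_cohort(cfg, seed = 2000 + s)
    sz <- st$params[st$params$group == "SZ" &
                      st$params$condition == "angry", ]
    m <- merge(sz, st$symptoms, by = "subject_id")
    abs(cor(m$frn, m$positive)) < 0.35
  }, TRUE)
  # null distribution of r at n = 38: P(|r| < 0.35) via the t transform
  r0 <- 0.35; df <- 38 - 2
  p_in <- 1 - 2 * pt(-r0 * sqrt(df / (1 - r0^2)), df)
  expect_lt(abs(mean(inside) - p_in),
            3 * sqrt(p_in * (1 - p_in) / n_seeds))
})

test_that("symptom scores have the configured moments and floor", {
  set.seed(21)
  z <- matrix(rnorm(4000 * 5), ncol = 5)
  s <- symptom_scores(z)
  expect_equal(mean(s$positive), 8.39, tolerance = 0.2)
  expect_equal(names(s),
               c("positive", "negative", "cognitive", "excitement",
                 "depressive"))
  expect_true(all(s$positive >= 4))   # 4 items x 1 point floor
  expect_true(all(s$depressive >= 3))

  degenerate <- symptom_scores(z, sds = rep(0, 5) + 1e-12)
  expect_true(all(abs(degenerate$positive - 8.39) < 1e-6))
})

test_that("an infeasible planted correlation matrix is rejected", {
  bad <- matrix(0.9, 4, 5)
  expect_error(cohort_config(planted_cor = bad), "positive-semi-definite")
})

test_that("regenerated session EEG is deterministic and truth-tagged", {
  cfg <- cohort_config(n_sz = 1, n_ctrl = 1, task = tiny_task_config(40),
                       eeg = list(srate = 250, noise_sd = 5,
                                  pink_exponent = 0, blink_rate = 0,
                                  enabled = TRUE))
  st <- generate_cohort(cfg, seed = 5)
  id <- st$roster$subject_id[1]
  e1 <- cohort_eeg(st, id, "angry")
  e2 <- cohort_eeg(st, id, "angry")
  expect_identical(e1$data, e2$data)
  expect_equal(nrow(e1$events), 2 * 40)
  p <- st$params[st$params$subject_id == id &
                   st$params$condition == "angry", ]
  expect_equal(attr(e1, "truth")$frn, p$frn)
})

test_that("zero-amplitude templates yield near-zero measured components", {
  set.seed(30)
  n <- 200
  tr <- data.frame(deck_class = rep(c("rich", "poor"), n / 2),
                   reward = rep(c(0, 1), n / 2))
  eeg <- synth_eeg(tr, erp_templates(0, 0, 0), srate = 250,
                   noise_sd = 10, seed = 31)
  amp <- erp_amplitudes(eeg, tr)
  # ~0.1 uV SEM scale; allow 4x
  expect_lt(abs(amp$n170), 0.8)
  expect_lt(abs(amp$p200), 0.8)
  expect_lt(abs(amp$frn), 0.8)
})

test_that("single-trial noiseless P200 equals the analytic window mean", {
  tr <- data.frame(deck_class = "rich", reward = 1)
  tmpl <- erp_templates(n170 = 0, p200 = 5, frn = 0)
  eeg <- synth_eeg(tr, tmpl, srate = 1000, noise_sd = 0, seed = 1)
  amp <- erp_amplitudes(eeg, tr, filter = FALSE)
  cw <- component_windows()
  analytic <- gauss_window_mean(tmpl$p200$peak, 200, 25,
                                cw$p200$window_ms) *
    mean(tmpl$p200$weights[cw$p200$channels])
  expect_equal(amp$p200, analytic, tolerance = 0.01)
  expect_equal(analytic, 5, tolerance = 0.01)
})

test_that("group behavior orderings hold on a default-size cohort", {
  # spot check; the seeded 10-replicate direction property (behavioral and
  # FRN arms) lives in the acceptance suite
  st <- generate_cohort(cohort_config(), seed = 3001)
  b <- merge(behavior_summary(st$trials), st$roster, by = "subject_id")
  ag <- aggregate(b[c("win_stay", "lose_shift", "total_score")],
                  by = list(group = b$group), mean, na.rm = TRUE)
  sz <- ag[ag$group == "SZ", ]; ct <- ag[ag$group == "CTRL", ]
  expect_lt(sz$total_score, ct$total_score)
  expect_lt(sz$win_stay, ct$win_stay)
  expect_gt(sz$lose_shift, ct$lose_shift)
})
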