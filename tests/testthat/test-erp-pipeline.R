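make_sine_eeg <- function(freq, amp = 1, dur_s = 60, srate = 1000,
                          dc = 0) {
  t <- seq_len(dur_s * srate) / srate
  eeg_continuous(matrix(dc + amp * sin(2 * pi * freq * t), ncol = 1),
                 channels = "Cz", srate = srate)
}

test_that("bandpass passes 10 Hz, removes DC, and attenuates 60 Hz", {
  mid <- function(x) x[20000:40000]   # steady-state interior

  passed <- bandpass(make_sine_eeg(10))
  expect_lt(abs(max(abs(mid(passed$data[, 1]))) - 1), 0.05)

  dc <- bandpass(make_sine_eeg(0, amp = 0, dc = 100))
  expect_lt(max(abs(mid(dc$data[, 1]))), 5)

  hum <- bandpass(make_sine_eeg(60))
  expect_lt(max(abs(mid(hum$data[, 1]))), 10^(-20 / 20))

  expect_error(bandpass(make_sine_eeg(10), low = 50, high = 40),
               "band edges")
})

test_that("epoching yields half-open windows and skips boundary events", {
  dat <- matrix(rnorm(5000), ncol = 2)
  ev <- data.frame(sample = c(500, 1500), code = "prime")
  eeg <- eeg_continuous(dat, c("Fz", "Cz"), 1000, ev)
  ep <- epoch(eeg, "prime", c(-100, 500))
  expect_equal(dim(ep$data), c(2, 2, 600))
  expect_equal(ep$n_skipped, 0L)
  # first sample corresponds to window start (-100 ms)
  expect_equal(ep$data[1, 1, 1], dat[400, 1])
  expect_equal(ep$data[1, 1, 600], dat[999, 1])

  ev2 <- data.frame(sample = c(50, 1500), code = "prime")
  eeg2 <- eeg_continuous(dat, c("Fz", "Cz"), 1000, ev2)
  ep2 <- epoch(eeg2, "prime", c(-100, 500))
  expect_equal(dim(ep2$data)[1], 1L)
  expect_equal(ep2$n_skipped, 1L)

  expect_error(epoch(eeg, "nope", c(-100, 500)), "no events")
})

test_that("constant signals produce constant epochs and zero baselines", {
  dat <- matrix(5, 2000, 1)
  eeg <- eeg_continuous(dat, "Fz", 1000,
                        data.frame(sample = 1000, code = "x"))
  ep <- baseline_correct(epoch(eeg, "x", c(-100, 500)))
  expect_true(all(abs(ep$data) < 1e-12))
})

test_that("baseline correction zeroes the prestimulus mean", {
  set.seed(3)
  dat <- matrix(rnorm(6000, 10, 4), ncol = 2)
  eeg <- eeg_continuous(dat, c("Fz", "Cz"), 1000,
                        data.frame(sample = c(1000, 2000), code = "x"))
  ep <- baseline_correct(epoch(eeg, "x", c(-100, 900)))
  tms <- ep$window_ms[1] + (seq_len(dim(ep$data)[3]) - 1)
  pre <- tms < 0
  for (e in 1:2) for (ch in 1:2)
    expect_lt(abs(mean(ep$data[e, ch, pre])), 1e-9)
})

test_that("baseline-corrected ramp matches closed-form arithmetic", {
  # 0 -> 1 uV linear ramp across a -100..900 ms epoch
  ramp <- seq(0, 1, length.out = 1000)
  dat <- matrix(c(rep(0, 500), ramp, rep(1, 500)), ncol = 1)
  eeg <- eeg_continuous(dat, "Fz", 1000,
                        data.frame(sample = 601, code = "x"))
  ep <- baseline_correct(epoch(eeg, "x", c(-100, 900)))
  at0 <- ep$data[1, 1, 101]        # first poststimulus sample
  expected <- ramp[101] - mean(ramp[1:100])
  expect_equal(at0, expected, tolerance = 1e-12)
})

test_that("artifact rejection is strict and retains exact counts", {
  set.seed(4)
  arr <- array(rnorm(10 * 2 * 100, 0, 5), c(10, 2, 100))
  arr[arr > 45] <- 45; arr[arr < -45] <- -45
  spiky <- c(2, 5, 9)
  for (e in spiky) arr[e, 1, 50] <- 51
  ep <- epochs_from_array(arr, c("Fz", "Cz"), c(-100, 0), 1000)
  ep <- reject_artifacts(ep, threshold = 50, channels = c("Fz", "Cz"))
  expect_equal(sum(ep$retained), 7L)
  expect_equal(which(!ep$retained), spiky)

  # exactly +/- 50.0 is retained (strict inequality)
  arr2 <- array(0, c(1, 1, 10)); arr2[1, 1, 3] <- 50
  ep2 <- reject_artifacts(
    epochs_from_array(arr2, "Fz", c(-100, 0), 1000), channels = "Fz")
  expect_true(ep2$retained)
  arr2[1, 1, 3] <- 50.0001
  ep3 <- reject_artifacts(
    epochs_from_array(arr2, "Fz", c(-100, 0), 1000), channels = "Fz")
  expect_false(ep3$retained)
})

test_that("feedback expectancy classification follows deck class x reward", {
  expect_equal(classify_feedback("poor", 1), "unexpected_win")
  expect_equal(classify_feedback("rich", 0), "unexpected_loss")
  expect_equal(classify_feedback("rich", 1), "expected_win")
  expect_equal(classify_feedback("poor", 0), "expected_loss")
  expect_error(classify_feedback("middle", 1), "rich")
  expect_error(classify_feedback(NA_character_, 1), "rich")
})

test_that("averaging uses retained epochs only and obeys the SEM bound", {
  arr <- array(0, c(2, 1, 10))
  arr[1, 1, ] <- 1; arr[2, 1, ] <- -1
  ep <- epochs_from_array(arr, "Fz", c(0, 10), 1000)
  expect_true(all(average_erp(ep)$data == 0))

  # rejecting then averaging equals averaging the retained subset
  arr3 <- array(rnorm(5 * 1 * 20), c(5, 1, 20))
  arr3[4, 1, 7] <- 100
  ep3 <- reject_artifacts(epochs_from_array(arr3, "Fz", c(0, 20), 1000),
                          channels = "Fz")
  manual <- apply(arr3[-4, 1, , drop = FALSE], 3, mean)
  expect_equal(as.vector(average_erp(ep3)$data), manual)

  # noisy template recovery within 3 * SEM
  set.seed(6)
  template <- 5 * sin(seq(0, pi, length.out = 100))
  n_ep <- 200; noise_sd <- 10
  arr4 <- array(NA_real_, c(n_ep, 1, 100))
  for (e in seq_len(n_ep))
    arr4[e, 1, ] <- template + rnorm(100, 0, noise_sd)
  avg <- average_erp(epochs_from_array(arr4, "Fz", c(0, 100), 1000))
  rmse <- sqrt(mean((avg$data - template)^2))
  expect_lte(rmse, 3 * noise_sd / sqrt(n_ep))

  expect_error(average_erp(ep, select = c(FALSE, FALSE)), "no retained")
})

test_that("FRN difference wave subtracts pointwise with axis checks", {
  loss <- erp_from_matrix(matrix(-5, 1, 100), "FCz", c(-100, 0), 1000)
  win <- erp_from_matrix(matrix(-1, 1, 100), "FCz", c(-100, 0), 1000)
  d <- frn_difference(loss, win)
  expect_true(all(d$data == -4))
  expect_true(all(frn_difference(loss, loss)$data == 0))
  other <- erp_from_matrix(matrix(0, 1, 100), "Cz", c(-100, 0), 1000)
  expect_error(frn_difference(loss, other), "match")
})

test_that("mean amplitude windows are half-open and channel-averaged", {
  cw <- component_windows()
  m <- matrix(2, 3, 1000)
  erp <- erp_from_matrix(m, c("Fz", "FCz", "Cz"), c(-100, 900), 1000)
  expect_equal(mean_amplitude(erp, c(300, 600), c("Fz", "FCz", "Cz")), 2)

  # -4 uV confined to 300-600 ms
  m2 <- matrix(0, 3, 1000)
  tms <- -100 + 0:999
  m2[, tms >= 300 & tms < 600] <- -4
  erp2 <- erp_from_matrix(m2, c("Fz", "FCz", "Cz"), c(-100, 900), 1000)
  expect_equal(mean_amplitude(erp2, cw$frn$window_ms, cw$frn$channels), -4)

  # Gaussian component vs analytic window average
  a <- 6
  g <- a * exp(-((-100 + 0:599) - 200)^2 / (2 * 20^2))
  erp3 <- erp_from_matrix(rbind(g, g, g), c("Fz", "Cz", "Pz"),
                          c(-100, 500), 1000)
  analytic <- gauss_window_mean(a, 200, 20, cw$p200$window_ms)
  expect_lt(abs(mean_amplitude(erp3, cw$p200$window_ms, cw$p200$channels) -
                  analytic), 1e-3 * a)

  expect_error(mean_amplitude(erp3, c(400, 600), "Fz"), "inside")
  expect_error(mean_amplitude(erp3, c(170, 230), "P9"), "not present")
})

test_that("injected components are recovered through the full pipeline", {
  set.seed(11)
  n <- 480
  tr <- data.frame(deck_class = sample(c("rich", "poor"), n, TRUE,
                                       prob = c(0.5, 0.5)),
                   reward = rbinom(n, 1, 0.5))
  eeg <- synth_eeg(tr, erp_templates(n170 = -5, p200 = 5, frn = -3),
                   srate = 250, noise_sd = 10, seed = 12)
  amp <- erp_amplitudes(eeg, tr)
  expect_gte(amp$n_unexpected_win, 80)
  expect_gte(amp$n_unexpected_loss, 80)
  expect_lt(abs(amp$n170 - (-5)), 0.5)
  expect_lt(abs(amp$p200 - 5), 0.5)
  expect_lt(abs(amp$frn - (-3)), 0.5)
})

test_that("the pipeline is linear in the input scale", {
  set.seed(13)
  n <- 60
  tr <- data.frame(deck_class = rep(c("rich", "poor"), n / 2),
                   reward = rep(c(0, 1), n / 2))
  eeg <- synth_eeg(tr, erp_templates(-4, 4, -2), srate = 250,
                   noise_sd = 5, seed = 14)
  amp1 <- erp_amplitudes(eeg, tr)
  half <- eeg; half$data <- eeg$data * 0.5
  amp2 <- erp_amplitudes(half, tr)
  for (k in c("n170", "p200", "frn"))
    expect_equal(amp2[[k]], amp1[[k]] * 0.5, tolerance = 1e-9)
})

test_that("blink-like transients are caught by rejection", {
  set.seed(15)
  n <- 40
  tr <- data.frame(deck_class = rep(c("rich", "poor"), n / 2),
                   reward = rep(c(0, 1), n / 2))
  eeg <- synth_eeg(tr, erp_templates(0, 0, 0), srate = 250,
                   noise_sd = 3, blink_rate = 30, seed = 16)
  ep <- reject_artifacts(baseline_correct(epoch(eeg, "prime",
                                                c(-100, 500))))
  expect_gt(sum(!ep$retained), 0)
})
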