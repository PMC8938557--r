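#' ERP component templates for synthetic EEG
#'
#' Defines the injected Gaussian-shaped components. Amplitudes are given as
#' the *target mean amplitude* each component should produce in its standard
#' analysis window (see [component_windows()]); peak heights are derived
#' internally from the Gaussian window average and the channel weighting, so
#' a template with `frn = -3` yields a difference-wave FRN of about -3 uV
#' under the extraction pipeline. The N170 is right-lateralized (P7 weighted
#' 0.815 relative to P8, matching the reported P7/P8 asymmetry); the P200 is
#' frontocentral; the FRN effect is added on unexpected-loss trials only, so
#' the loss-minus-win difference wave recovers it.
#'
#' @param n170,p200,frn Target window-mean amplitudes in uV (N170 and FRN
#'   are conventionally negative).
#' @param n170_latency,p200_latency,frn_latency Peak latencies in ms
#'   post-event.
#' @param n170_sd,p200_sd,frn_sd Gaussian temporal widths in ms.
#' @return An object of class `erp_templates`.
#' @examples
#' erp_templates(n170 = -5, p200 = 5, frn = -3.9)
#' @export
erp_templates <- function(n170 = -5, p200 = 5, frn = -3.9,
                          n170_latency = 180, p200_latency = 200,
                          frn_latency = 450,
                          n170_sd = 20, p200_sd = 25, frn_sd = 60) {
  cw <- component_windows()
  comp <- function(target, latency, sd_ms, weights, window, lock) {
    w_mean <- mean(weights[cw_channels(window)])
    peak <- if (target == 0) 0 else
      target / (gauss_window_mean(1, latency, sd_ms, window$window_ms) * w_mean)
    list(target = target, latency = latency, sd_ms = sd_ms,
         weights = weights, peak = peak, lock = lock)
  }
  structure(list(
    n170 = comp(n170, n170_latency, n170_sd,
                c(P7 = 0.815, P8 = 1), cw$n170, "prime"),
    p200 = comp(p200, p200_latency, p200_sd,
                c(Fz = 1, FCz = 1, Cz = 1, Pz = 0.8), cw$p200, "prime"),
    frn = comp(frn, frn_latency, frn_sd,
               c(Fz = 1, FCz = 1, Cz = 1), cw$frn, "feedback")),
    class = "erp_templates")
}

# channels of a component definition that enter its mean amplitude
cw_channels <- function(window_def) window_def$channels

#' Analytic window average of a Gaussian component
#'
#' Mean over `[a, b)` of `peak * exp(-(t - latency)^2 / (2 sd^2))`, i.e.
#' `peak * sd * sqrt(2 pi) * (Phi((b-latency)/sd) - Phi((a-latency)/sd)) /
#' (b - a)`. Used both to calibrate template peaks and as the closed-form
#' oracle in injection-recovery checks.
#'
#' @param peak Peak amplitude in uV.
#' @param latency Peak latency in ms.
#' @param sd_ms Gaussian width in ms.
#' @param window_ms Length-2 window `c(a, b)` in ms.
#' @return Scalar mean amplitude in uV.
#' @export
gauss_window_mean <- function(peak, latency, sd_ms, window_ms) {
  a <- window_ms[1]; b <- window_ms[2]
  peak * sd_ms * sqrt(2 * pi) *
    (pnorm((b - latency) / sd_ms) - pnorm((a - latency) / sd_ms)) / (b - a)
}

# 1/f^expo-shaped Gaussian noise via spectral shaping (expo = 0 is white)
shaped_noise <- function(n, sd, expo) {
  if (expo == 0) return(rnorm(n, 0, sd))
  x <- rnorm(n)
  xf <- stats::fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  scale <- f^(-expo / 2)
  y <- Re(stats::fft(xf * scale, inverse = TRUE)) / n
  y * sd / sd(y)
}

#' Synthesize continuous EEG for one subject x condition session
#'
#' Generates an epoch-aligned continuous record (one stretch per trial,
#' default 2.2 s) over the six analysis channels (P7, P8, Fz, FCz, Cz, Pz)
#' with one `prime` and one `feedback` event per trial, injects the
#' template components (N170 and P200 on every prime; the FRN effect on
#' unexpected-loss feedbacks only), and adds Gaussian noise (optionally
#' 1/f-shaped). Optional eyeblink-like frontal transients can be injected
#' to exercise artifact rejection. Ground-truth template amplitudes are
#' attached as an attribute.
#'
#' @param trials Trial table for the session (columns `deck_class`,
#'   `reward`), one row per trial in order.
#' @param templates An [erp_templates()].
#' @param srate Sampling rate in Hz.
#' @param noise_sd White-noise standard deviation in uV.
#' @param pink_exponent Spectral exponent of the noise (0 = white).
#' @param blink_rate Expected blink artifacts per minute (0 disables).
#' @param trial_s Length of each trial stretch in seconds; prime onset at
#'   0.2 s, feedback onset 0.7 s later. Must leave both epochs inside the
#'   stretch.
#' @param seed Optional integer seed.
#' @return An [eeg_continuous()] with `prime` and `feedback` events and a
#'   `truth` attribute.
#' @export
synth_eeg <- function(trials, templates = erp_templates(), srate = 1000,
                      noise_sd = 10, pink_exponent = 0, blink_rate = 0,
                      trial_s = 2.2, seed = NULL) {
  stopifnot(inherits(templates, "erp_templates"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  channels <- c("P7", "P8", "Fz", "FCz", "Cz", "Pz")
  n_trials <- nrow(trials)
  L <- round(trial_s * srate)
  prime_off <- round(0.2 * srate)
  fb_gap <- round(0.7 * srate)
  # epoch spans: prime -100..500, feedback -100..900 ms
  if (fb_gap < round(0.6 * srate) ||
      L - prime_off - fb_gap < round(1.0 * srate))
    stop("trial stretch too short: events closer than their epoch spans")
  n <- n_trials * L
  dat <- matrix(0, n, length(channels))
  for (j in seq_along(channels))
    dat[, j] <- shaped_noise(n, noise_sd, pink_exponent)
  colnames(dat) <- channels

  prime_samp <- (seq_len(n_trials) - 1L) * L + prime_off + 1L
  fb_samp <- prime_samp + fb_gap
  expect <- classify_feedback(trials$deck_class, trials$reward)

  # Gaussian kernel centered `latency` ms after each onset sample
  add_component <- function(comp, onsets, which_trials = NULL) {
    if (comp$peak == 0) return()
    if (!is.null(which_trials)) onsets <- onsets[which_trials]
    if (!length(onsets)) return()
    half <- round(4 * comp$sd_ms * srate / 1000)
    rel <- (-half):half
    shape <- comp$peak * exp(-(rel * 1000 / srate)^2 / (2 * comp$sd_ms^2))
    center <- round(comp$latency * srate / 1000)
    for (ch in names(comp$weights)) {
      j <- match(ch, channels)
      if (is.na(j)) next
      w <- comp$weights[[ch]]
      for (s in onsets) {
        idx <- s + center + rel
        ok <- idx >= 1 & idx <= n
        dat[idx[ok], j] <<- dat[idx[ok], j] + w * shape[ok]
      }
    }
  }
  add_component(templates$n170, prime_samp)
  add_component(templates$p200, prime_samp)
  add_component(templates$frn, fb_samp, expect == "unexpected_loss")

  if (blink_rate > 0) {
    n_blinks <- rbinom(1, n, blink_rate / (60 * srate))
    if (n_blinks > 0) {
      at <- sample.int(n - srate, n_blinks)
      blen <- round(0.1 * srate)
      bshape <- 80 * sin(pi * seq_len(blen) / blen)
      for (s in at) {
        for (ch in c("Fz", "FCz")) {
          j <- match(ch, channels)
          dat[s:(s + blen - 1L), j] <- dat[s:(s + blen - 1L), j] + bshape
        }
      }
    }
  }

  ev <- data.frame(
    sample = c(prime_samp, fb_samp),
    code = rep(c("prime", "feedback"), each = n_trials))
  ev <- ev[order(ev$sample), ]
  out <- eeg_continuous(dat, channels, srate, ev)
  attr(out, "truth") <- list(
    n170 = templates$n170$target, p200 = templates$p200$target,
    frn = templates$frn$target,
    n_unexpected_loss = sum(expect == "unexpected_loss"),
    n_unexpected_win = sum(expect == "unexpected_win"))
  out
}
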