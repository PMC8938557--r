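#' Continuous multichannel EEG container
#'
#' @param data Numeric matrix, samples x channels, in microvolts.
#' @param channels Character vector of 10-20 channel labels.
#' @param srate Sampling rate in Hz.
#' @param events Data frame with columns `sample` (1-based sample index of
#'   event onset) and `code` (character event label).
#' @return An object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, channels, srate = 1000,
                           events = data.frame(sample = integer(),
                                               code = character())) {
  data <- as.matrix(data)
  if (ncol(data) != length(channels))
    stop("one channel label per data column required")
  if (srate <= 0) stop("sampling rate must be positive")
  if (nrow(events) &&
      (any(events$sample < 1) || any(events$sample > nrow(data))))
    stop("event samples must lie within the record")
  colnames(data) <- channels
  structure(list(data = data, channels = channels, srate = srate,
                 events = events),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("Continuous EEG: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              length(x$channels), nrow(x$data), x$srate,
              nrow(x$data) / x$srate, nrow(x$events)))
  invisible(x)
}

#' Default ERP analysis windows and channel sets
#'
#' N170: 150--210 ms at P7/P8 (prime-locked); P200: 170--230 ms at
#' Fz/Cz/Pz (prime-locked); FRN: 300--600 ms at Fz/FCz/Cz
#' (feedback-locked difference wave). Prime epochs span -100..500 ms,
#' feedback epochs -100..900 ms; the baseline window is \[-100, 0) ms.
#'
#' @return Named list of component definitions (`window_ms`, `channels`,
#'   `epoch_ms`, `lock`).
#' @export
component_windows <- function() {
  list(
    n170 = list(window_ms = c(150, 210), channels = c("P7", "P8"),
                epoch_ms = c(-100, 500), lock = "prime"),
    p200 = list(window_ms = c(170, 230), channels = c("Fz", "Cz", "Pz"),
                epoch_ms = c(-100, 500), lock = "prime"),
    frn = list(window_ms = c(300, 600), channels = c("Fz", "FCz", "Cz"),
               epoch_ms = c(-100, 900), lock = "feedback"))
}

#' Zero-phase 0.1--40 Hz bandpass filter
#'
#' Band-limits each channel with cascaded zero-phase Butterworth stages
#' (2nd-order high-pass at `low`, 4th-order low-pass at `high`, each applied
#' forward-backward via [signal::filtfilt()]); the cascade keeps the very
#' low high-pass corner numerically stable at EEG sampling rates. Events
#' are preserved.
#'
#' @param eeg An [eeg_continuous()].
#' @param low,high Band edges in Hz; require `0 < low < high < srate/2`.
#' @return Filtered `eeg_continuous`.
#' @export
bandpass <- function(eeg, low = 0.1, high = 40) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  nyq <- eeg$srate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < srate/2")
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  out <- eeg
  for (j in seq_along(eeg$channels)) {
    x <- signal::filtfilt(hp, eeg$data[, j])
    out$data[, j] <- signal::filtfilt(lp, x)
  }
  out
}

#' Extract event-locked epochs
#'
#' Cuts one epoch per event of the requested code, over a half-open window
#' `[start, end)` ms relative to event onset (0 ms is the first
#' poststimulus sample). Events whose window would extend beyond the record
#' are skipped and counted.
#'
#' @param eeg An [eeg_continuous()].
#' @param event_code Event label to epoch on.
#' @param window_ms Length-2 window in ms, e.g. `c(-100, 900)`.
#' @return An object of class `epoch_set`: list with `data` (array
#'   epochs x channels x time), `window_ms`, `srate`, `channels`, `codes`,
#'   `retained` (logical rejection mask, all `TRUE` initially),
#'   `n_skipped`, `baseline_corrected`.
#' @export
epoch <- function(eeg, event_code, window_ms) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  ev <- eeg$events[eeg$events$code == event_code, , drop = FALSE]
  if (!nrow(ev)) stop(sprintf("no events with code '%s'", event_code))
  s0 <- round(window_ms[1] * eeg$srate / 1000)
  s1 <- round(window_ms[2] * eeg$srate / 1000)
  n_time <- s1 - s0
  usable <- ev$sample + s0 >= 1 & ev$sample + s1 - 1 <= nrow(eeg$data)
  n_skipped <- sum(!usable)
  ev <- ev[usable, , drop = FALSE]
  if (!nrow(ev))
    stop(sprintf("no usable events with code '%s' (%d skipped at boundaries)",
                 event_code, n_skipped))
  arr <- array(NA_real_, dim = c(nrow(ev), length(eeg$channels), n_time))
  idx <- seq.int(s0, s1 - 1L)
  for (e in seq_len(nrow(ev)))
    arr[e, , ] <- t(eeg$data[ev$sample[e] + idx, , drop = FALSE])
  structure(list(data = arr, window_ms = window_ms, srate = eeg$srate,
                 channels = eeg$channels, codes = rep(event_code, nrow(ev)),
                 event_samples = ev$sample,
                 retained = rep(TRUE, nrow(ev)), n_skipped = n_skipped,
                 baseline_corrected = FALSE),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "Epoch set: %d epochs (%d retained) x %d channels x %d samples, %g-%g ms @ %g Hz\n",
    dim(x$data)[1], sum(x$retained), dim(x$data)[2], dim(x$data)[3],
    x$window_ms[1], x$window_ms[2], x$srate))
  invisible(x)
}

# time axis (ms) of each sample in an epoch, first sample = window start
epoch_times <- function(epochs) {
  s0 <- round(epochs$window_ms[1] * epochs$srate / 1000)
  (s0 + seq_len(dim(epochs$data)[3]) - 1L) * 1000 / epochs$srate
}

#' Baseline-correct epochs against the prestimulus window
#'
#' Per epoch and channel, subtracts the mean over the prestimulus interval
#' `[window start, 0)` ms.
#'
#' @param epochs An [epoch()] result whose window includes prestimulus
#'   samples.
#' @return Baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  tms <- epoch_times(epochs)
  pre <- tms < 0
  if (!any(pre))
    stop("epoch window contains no prestimulus samples")
  bl <- apply(epochs$data[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)   # recycled over time (3rd dim)
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Threshold-based artifact rejection
#'
#' Marks an epoch rejected iff any sample on any of the analysis channels
#' exceeds the threshold in absolute value (strict inequality: exactly
#' +/-50.0 uV is retained). The mask depends only on the samples and the
#' threshold, never on event labels.
#'
#' @param epochs A baseline-corrected [epoch_set].
#' @param threshold Microvolt threshold (default 50).
#' @param channels Channels inspected for artifacts; default the six
#'   analysis channels present in the data.
#' @return `epoch_set` with an updated `retained` mask.
#' @export
reject_artifacts <- function(epochs, threshold = 50,
                             channels = intersect(
                               c("P7", "P8", "Fz", "FCz", "Cz", "Pz"),
                               epochs$channels)) {
  stopifnot(inherits(epochs, "epoch_set"))
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("unknown rejection channel(s)")
  mx <- apply(abs(epochs$data[, ci, , drop = FALSE]), 1, max)
  epochs$retained <- mx <= threshold
  epochs
}

#' Classify a feedback trial's expectancy
#'
#' Reward from the poor deck is an unexpected win; non-reward from the rich
#' deck an unexpected loss; the complementary cells are expected outcomes.
#'
#' @param deck_class "rich" or "poor" (vectorized).
#' @param reward 0/1 (vectorized).
#' @return Character vector in \{"expected_win", "unexpected_win",
#'   "expected_loss", "unexpected_loss"\}.
#' @export
classify_feedback <- function(deck_class, reward) {
  if (anyNA(deck_class) || !all(deck_class %in% c("rich", "poor")))
    stop("deck_class must be 'rich' or 'poor'")
  if (!all(reward %in% c(0, 1))) stop("reward must be 0/1")
  ifelse(deck_class == "poor",
         ifelse(reward == 1, "unexpected_win", "expected_loss"),
         ifelse(reward == 1, "expected_win", "unexpected_loss"))
}

#' Average retained epochs into an ERP waveform
#'
#' @param epochs An [epoch_set].
#' @param select Optional logical vector over epochs (e.g. an expectancy
#'   selection); combined with the rejection mask.
#' @param label Condition/expectancy label stored on the waveform.
#' @return An object of class `erp_waveform`: list with `data` (matrix
#'   channels x time, uV), `channels`, `srate`, `window_ms`, `n` (epochs
#'   averaged), `label`.
#' @export
average_erp <- function(epochs, select = NULL, label = "") {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- epochs$retained
  if (!is.null(select)) {
    if (length(select) != length(keep))
      stop("`select` must have one entry per epoch")
    keep <- keep & select
  }
  if (!any(keep))
    stop(sprintf(
      "no retained epochs to average (0 of %d selected, %d rejected)",
      length(keep), sum(!epochs$retained)))
  m <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  structure(list(data = m, channels = epochs$channels, srate = epochs$srate,
                 window_ms = epochs$window_ms, n = sum(keep), label = label),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("ERP waveform '%s': %d channels, %g-%g ms @ %g Hz, %d epochs\n",
              x$label, length(x$channels), x$window_ms[1], x$window_ms[2],
              x$srate, x$n))
  invisible(x)
}

#' FRN difference wave (unexpected loss minus unexpected win)
#'
#' @param loss_erp,win_erp [average_erp()] waveforms on matching channels,
#'   window and sampling rate.
#' @return `erp_waveform` of the pointwise difference.
#' @export
frn_difference <- function(loss_erp, win_erp) {
  stopifnot(inherits(loss_erp, "erp_waveform"),
            inherits(win_erp, "erp_waveform"))
  if (!identical(loss_erp$channels, win_erp$channels) ||
      !identical(loss_erp$window_ms, win_erp$window_ms) ||
      !identical(loss_erp$srate, win_erp$srate))
    stop("waveform axes (channels, window, rate) must match")
  out <- loss_erp
  out$data <- loss_erp$data - win_erp$data
  out$n <- min(loss_erp$n, win_erp$n)
  out$label <- "unexpected_loss - unexpected_win"
  out
}

#' Mean amplitude over a component window
#'
#' Mean of the waveform over the half-open window `[start, end)` ms across
#' the listed channels, channels weighted equally.
#'
#' @param erp An [average_erp()] / [frn_difference()] waveform.
#' @param window_ms Length-2 analysis window in ms.
#' @param channels Channels to aggregate.
#' @return Scalar mean amplitude in microvolts.
#' @export
mean_amplitude <- function(erp, window_ms, channels) {
  stopifnot(inherits(erp, "erp_waveform"))
  ci <- match(channels, erp$channels)
  if (anyNA(ci))
    stop(sprintf("channel(s) not present: %s",
                 paste(channels[is.na(ci)], collapse = ", ")))
  tms <- epoch_times(list(window_ms = erp$window_ms, srate = erp$srate,
                          data = array(0, c(1, 1, ncol(erp$data)))))
  if (window_ms[1] < erp$window_ms[1] || window_ms[2] > erp$window_ms[2])
    stop("analysis window must lie inside the epoch window")
  sel <- tms >= window_ms[1] & tms < window_ms[2]
  mean(erp$data[ci, sel, drop = FALSE])
}

#' Extract the three component amplitudes for one subject x condition
#'
#' Full pipeline wrapper: bandpass, epoch on prime and feedback events,
#' baseline-correct, reject artifacts, average (expectancy-split for the
#' FRN), and measure mean amplitudes in the standard windows.
#'
#' @param eeg An [eeg_continuous()] with `prime` and `feedback` events, one
#'   of each per trial in trial order.
#' @param trials Trial table aligned with the feedback events (columns
#'   `deck_class`, `reward`).
#' @param filter Apply the 0.1--40 Hz bandpass first (default `TRUE`).
#' @param reject_threshold Artifact threshold in uV.
#' @return Named list: `n170`, `p200`, `frn` (mean amplitudes in uV),
#'   `n_unexpected_win`, `n_unexpected_loss`, `n_rejected_prime`,
#'   `n_rejected_feedback`.
#' @export
erp_amplitudes <- function(eeg, trials, filter = TRUE,
                           reject_threshold = 50) {
  cw <- component_windows()
  if (filter) eeg <- bandpass(eeg)

  pe <- reject_artifacts(baseline_correct(epoch(eeg, "prime",
                                                cw$n170$epoch_ms)),
                         threshold = reject_threshold)
  prime_erp <- average_erp(pe, label = "prime")

  fe <- reject_artifacts(baseline_correct(epoch(eeg, "feedback",
                                                cw$frn$epoch_ms)),
                         threshold = reject_threshold)
  expect <- classify_feedback(trials$deck_class, trials$reward)
  if (length(expect) != dim(fe$data)[1] + fe$n_skipped)
    stop("trial table does not align with feedback events")
  if (fe$n_skipped) expect <- expect[seq_len(dim(fe$data)[1])]
  uw <- expect == "unexpected_win"
  ul <- expect == "unexpected_loss"
  frn_amp <- if (any(uw & fe$retained) && any(ul & fe$retained)) {
    d <- frn_difference(average_erp(fe, ul, "unexpected_loss"),
                        average_erp(fe, uw, "unexpected_win"))
    mean_amplitude(d, cw$frn$window_ms, cw$frn$channels)
  } else NA_real_

  list(n170 = mean_amplitude(prime_erp, cw$n170$window_ms, cw$n170$channels),
       p200 = mean_amplitude(prime_erp, cw$p200$window_ms, cw$p200$channels),
       frn = frn_amp,
       n_unexpected_win = sum(uw & fe$retained),
       n_unexpected_loss = sum(ul & fe$retained),
       n_rejected_prime = sum(!pe$retained),
       n_rejected_feedback = sum(!fe$retained))
}
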