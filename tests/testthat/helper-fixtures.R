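# Shared fixtures and independent oracles, all built in code.

# spec-style toy sequence: deck A rich throughout
toy_trials <- function() {
  data.frame(
    subject_id = "t1", condition = "neutral", block = 1L,
    trial = 0:4,
    chosen_deck = c("A", "A", "B", "B", "A"),
    deck_class = c("rich", "rich", "poor", "poor", "rich"),
    reward = c(1L, 0L, 1L, 1L, 0L))
}

# naive trial-by-trial loop oracle for win-stay/lose-shift rates
naive_strategy_rates <- function(trials) {
  n <- nrow(trials)
  cnt <- list()
  for (fb in c("win", "lose")) for (cls in c("rich", "poor"))
    cnt[[paste(fb, cls)]] <- c(num = 0, den = 0)
  for (t in seq_len(n - 1)) {
    fb <- if (trials$reward[t] == 1) "win" else "lose"
    cls <- trials$deck_class[t]
    stay <- trials$chosen_deck[t + 1] == trials$chosen_deck[t]
    hit <- if (fb == "win") stay else !stay
    key <- paste(fb, cls)
    cnt[[key]]["den"] <- cnt[[key]]["den"] + 1
    cnt[[key]]["num"] <- cnt[[key]]["num"] + as.integer(hit)
  }
  rate <- function(key) {
    d <- cnt[[key]]["den"]
    if (d == 0) NA_real_ else unname(cnt[[key]]["num"] / d)
  }
  pooled <- function(fb) {
    d <- cnt[[paste(fb, "rich")]]["den"] + cnt[[paste(fb, "poor")]]["den"]
    nmr <- cnt[[paste(fb, "rich")]]["num"] + cnt[[paste(fb, "poor")]]["num"]
    if (d == 0) NA_real_ else unname(nmr / d)
  }
  list(win_stay_rich = rate("win rich"), win_stay_poor = rate("win poor"),
       lose_shift_rich = rate("lose rich"),
       lose_shift_poor = rate("lose poor"),
       win_stay = pooled("win"), lose_shift = pooled("lose"))
}

# random trial sequence with block-constant deck classes
random_trials <- function(n = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rich <- sample(c("A", "B"), 1)
  ch <- sample(c("A", "B"), n, replace = TRUE)
  data.frame(
    subject_id = "r", condition = "neutral", block = 1L,
    trial = seq_len(n) - 1L,
    chosen_deck = ch,
    deck_class = ifelse(ch == rich, "rich", "poor"),
    reward = rbinom(n, 1, 0.5))
}

# simulated multi-subject dataset at known group-level truth
recovery_dataset <- function(n_subjects = 20, mu_alpha = 0.30,
                             sigma_alpha = 0.10, mu_beta = 4.0,
                             sigma_beta = 1.0, seed = 42) {
  set.seed(seed)
  true_a <- pmin(pmax(rnorm(n_subjects, mu_alpha, sigma_alpha), 0.02), 0.98)
  true_b <- pmin(pmax(rnorm(n_subjects, mu_beta, sigma_beta), 0.2), 9.8)
  trials <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    sc <- make_block_schedule(task_config(),
                              seed = sample.int(1e6, 1))
    simulate_subject(true_a[i], true_b[i], sc,
                     seed = sample.int(1e6, 1),
                     subject_id = sprintf("s%02d", i))$trials
  }))
  list(trials = trials, alpha = true_a, beta = true_b)
}

# flat epoch_set built directly from an array (epochs x channels x time)
epochs_from_array <- function(arr, channels, window_ms, srate) {
  structure(list(data = arr, window_ms = window_ms, srate = srate,
                 channels = channels,
                 codes = rep("x", dim(arr)[1]),
                 event_samples = seq_len(dim(arr)[1]),
                 retained = rep(TRUE, dim(arr)[1]), n_skipped = 0L,
                 baseline_corrected = TRUE),
            class = "epoch_set")
}

erp_from_matrix <- function(m, channels, window_ms, srate, n = 1L) {
  structure(list(data = m, channels = channels, srate = srate,
                 window_ms = window_ms, n = n, label = ""),
            class = "erp_waveform")
}
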