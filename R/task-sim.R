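#' Configuration for the two-choice probabilistic gambling task
#'
#' Builds the task-environment configuration: the experimental phase consists
#' of a fixed number of trials pseudorandomly divided into blocks, each block
#' assigning a rich:poor reward-probability ratio to the two decks so that the
#' two probabilities sum to a fixed total. Defaults reproduce the standard
#' session: 480 experimental trials in six 70--90-trial blocks, a 60% total
#' reward probability, and a training probe after every 20 training trials.
#'
#' @param n_experimental_trials Total number of experimental-phase trials.
#' @param n_blocks Number of blocks the trials are divided into.
#' @param block_length_range Inclusive integer range (length 2) of admissible
#'   block lengths, in trials.
#' @param total_reward_prob Sum of the two decks' reward probabilities, in
#'   (0, 1].
#' @param ratio_set List of length-2 numeric vectors `c(rich, poor)` giving the
#'   admissible rich:poor ratios. The default set \{6:1, 1:6, 3:1, 1:3\}
#'   carries two configurable intermediate ratios alongside the extreme pair.
#' @param training_probe_after Number of training trials between deck-identity
#'   probes.
#' @param baited Reserved flag for baited (persistent) reward scheduling;
#'   only independent per-trial Bernoulli scheduling (`FALSE`) is implemented.
#'
#' @return An object of class `task_config` (a list of the above fields).
#' @examples
#' cfg <- task_config()
#' cfg$n_experimental_trials
#' @export
task_config <- function(n_experimental_trials = 480L,
                        n_blocks = 6L,
                        block_length_range = c(70L, 90L),
                        total_reward_prob = 0.60,
                        ratio_set = list(c(6, 1), c(1, 6), c(3, 1), c(1, 3)),
                        training_probe_after = 20L,
                        baited = FALSE) {
  n_experimental_trials <- as.integer(n_experimental_trials)
  n_blocks <- as.integer(n_blocks)
  block_length_range <- as.integer(block_length_range)
  if (length(block_length_range) != 2L ||
      block_length_range[1] > block_length_range[2])
    stop("`block_length_range` must be an inclusive integer range c(lo, hi)")
  if (!(total_reward_prob > 0 && total_reward_prob <= 1))
    stop("`total_reward_prob` must lie in (0, 1]")
  if (!length(ratio_set) || !all(vapply(ratio_set, length, 0L) == 2L))
    stop("`ratio_set` must be a list of c(rich, poor) pairs")
  if (any(unlist(ratio_set) <= 0))
    stop("ratio components must be positive")
  if (isTRUE(baited))
    stop("baited reward scheduling is reserved but not implemented")
  structure(
    list(n_experimental_trials = n_experimental_trials,
         n_blocks = n_blocks,
         block_length_range = block_length_range,
         total_reward_prob = total_reward_prob,
         ratio_set = ratio_set,
         training_probe_after = as.integer(training_probe_after),
         baited = FALSE),
    class = "task_config")
}

#' Reward probabilities of a deck pair from a ratio and a total
#'
#' Solves `p_rich / p_poor = ratio` and `p_rich + p_poor = total` so that a
#' 6:1 pair at a 60% total yields probabilities 0.5143 and 0.0857.
#'
#' @param ratio Length-2 positive numeric `c(rich, poor)`.
#' @param total Total reward probability in (0, 1].
#' @return A list with elements `p_rich` and `p_poor`, `p_rich >= p_poor`.
#' @examples
#' deck_probabilities(c(6, 1), 0.60)
#' @export
deck_probabilities <- function(ratio, total = 0.60) {
  if (length(ratio) != 2L || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("`ratio` must be two positive finite numbers")
  if (!is.finite(total) || total <= 0 || total > 1)
    stop("`total` must lie in (0, 1]")
  hi <- max(ratio); lo <- min(ratio)
  list(p_rich = total * hi / (hi + lo),
       p_poor = total * lo / (hi + lo))
}

#' Generate a block schedule for the experimental phase
#'
#' Draws block lengths as a uniform composition of the total trial count into
#' `n_blocks` parts constrained to the admissible range (rejection sampling
#' over the feasible set), then assigns each block a ratio drawn uniformly
#' from the ratio set with an independently randomized rich-deck side.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed; when supplied the schedule is a
#'   deterministic function of `(config, seed)`.
#' @return An object of class `block_schedule`: a data frame with one row per
#'   block and columns `block`, `length`, `start`, `end` (half-open 0-based
#'   trial bounds), `ratio_rich`, `ratio_poor`, `rich_deck` ("A" or "B"),
#'   `p_a`, `p_b`.
#' @examples
#' sched <- make_block_schedule(task_config(), seed = 1)
#' sum(sched$length)
#' @export
make_block_schedule <- function(config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_experimental_trials
  k <- config$n_blocks
  lo <- config$block_length_range[1]
  hi <- config$block_length_range[2]
  if (n < k * lo || n > k * hi)
    stop(sprintf(
      "infeasible schedule: %d trials cannot be split into %d blocks of %d-%d",
      n, k, lo, hi))
  if (!is.null(seed)) set.seed(as.integer(seed))

  lengths <- repeat_until_valid(k, n, lo, hi)
  ratio_idx <- sample.int(length(config$ratio_set), k, replace = TRUE)
  rich_side <- sample(c("A", "B"), k, replace = TRUE)

  ratios <- config$ratio_set[ratio_idx]
  pr <- lapply(ratios, deck_probabilities, total = config$total_reward_prob)
  p_rich <- vapply(pr, `[[`, 0, "p_rich")
  p_poor <- vapply(pr, `[[`, 0, "p_poor")
  ends <- cumsum(lengths)
  out <- data.frame(
    block = seq_len(k),
    length = lengths,
    start = c(0L, ends[-k]),
    end = ends,
    ratio_rich = vapply(ratios, max, 0),
    ratio_poor = vapply(ratios, min, 0),
    rich_deck = rich_side,
    p_a = ifelse(rich_side == "A", p_rich, p_poor),
    p_b = ifelse(rich_side == "A", p_poor, p_rich))
  class(out) <- c("block_schedule", "data.frame")
  out
}

# Uniform composition of n into k parts within [lo, hi]: draw k-1 parts
# uniformly, set the remainder last, accept iff the remainder is in range.
# Uniform over the feasible set because every admissible composition has the
# same proposal probability.
repeat_until_valid <- function(k, n, lo, hi) {
  if (k == 1L) return(n)
  repeat {
    first <- sample(lo:hi, k - 1L, replace = TRUE)
    last <- n - sum(first)
    if (last >= lo && last <= hi) return(c(first, last))
  }
}

#' Bernoulli reward feedback for a chosen deck
#'
#' @param p Reward probability of the chosen deck, in \[0, 1\]. Vectorized.
#' @return Integer vector of 0/1 rewards, one per element of `p`.
#' @examples
#' set.seed(1); sample_feedback(rep(0.5, 5))
#' @export
sample_feedback <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("reward probability must lie in [0, 1]")
  rbinom(length(p), 1L, p)
}

#' Run the training phase of the gambling task
#'
#' Participants play blocks of `training_probe_after` trials on a fixed deck
#' pair; after each block they are probed to identify the rich deck, and
#' training repeats until the answer is correct. `policy` stands in for the
#' participant: it receives the accumulated training trials and returns the
#' declared rich deck ("A" or "B").
#'
#' @param config A [task_config()].
#' @param policy Function `(trials) -> "A"|"B"` declaring the rich deck at a
#'   probe. The default declares the deck with the higher observed reward
#'   rate (ties broken at random).
#' @param choice_fun Function `(trials) -> "A"|"B"` selecting a deck on each
#'   training trial; the default chooses uniformly at random.
#' @param ratio Rich:poor ratio of the training deck pair.
#' @param rich_deck Which deck ("A" or "B") is rich during training.
#' @param seed Optional integer seed.
#' @param max_cycles Safety cap on probe cycles.
#' @return A list with `trials` (data frame: trial, chosen_deck, deck_class,
#'   reward), `first_probe_trial` (trial count at the first probe),
#'   `n_probes`, and `n_trials`.
#' @export
run_training_phase <- function(config = task_config(),
                               policy = NULL,
                               choice_fun = NULL,
                               ratio = c(6, 1),
                               rich_deck = "A",
                               seed = NULL,
                               max_cycles = 100L) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(choice_fun))
    choice_fun <- function(trials) sample(c("A", "B"), 1L)
  if (is.null(policy))
    policy <- function(trials) {
      rate <- tapply(trials$reward, trials$chosen_deck, mean)
      for (d in c("A", "B")) if (!d %in% names(rate)) rate[d] <- 0
      if (rate[["A"]] == rate[["B"]]) sample(c("A", "B"), 1L)
      else names(which.max(rate))
    }
  pp <- deck_probabilities(ratio, config$total_reward_prob)
  p_deck <- if (rich_deck == "A") c(A = pp$p_rich, B = pp$p_poor)
            else c(A = pp$p_poor, B = pp$p_rich)
  per <- config$training_probe_after
  trials <- NULL
  n_probes <- 0L
  first_probe_trial <- NA_integer_
  for (cycle in seq_len(max_cycles)) {
    for (t in seq_len(per)) {
      ch <- choice_fun(trials)
      rw <- sample_feedback(p_deck[[ch]])
      trials <- rbind(trials, data.frame(
        trial = nrow_or0(trials), chosen_deck = ch,
        deck_class = if (ch == rich_deck) "rich" else "poor",
        reward = rw))
    }
    n_probes <- n_probes + 1L
    if (is.na(first_probe_trial)) first_probe_trial <- nrow(trials)
    if (identical(policy(trials), rich_deck)) break
  }
  list(trials = trials, first_probe_trial = first_probe_trial,
       n_probes = n_probes, n_trials = nrow(trials))
}

nrow_or0 <- function(x) if (is.null(x)) 0L else nrow(x)

#' @export
print.block_schedule <- function(x, ...) {
  cat(sprintf("Block schedule: %d blocks, %d trials total\n",
              nrow(x), sum(x$length)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
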