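#' Delta-rule expectation update
#'
#' Updates a deck expectation toward the received outcome by a fraction
#' `alpha` of the reward prediction error:
#' `Q(t) = Q(t-1) + alpha * (R(t) - Q(t-1))`. Applied to the chosen deck
#' only; the unchosen deck's expectation is carried forward unchanged.
#'
#' @param q_prev Previous expectation. Vectorized.
#' @param reward Outcome in \{0, 1\} (any numeric outcome is accepted).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated expectation.
#' @examples
#' update_expectation(0.5, 1, 0.3) # 0.65
#' @export
update_expectation <- function(q_prev, reward, alpha) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("learning rate `alpha` must lie in [0, 1]")
  q_prev + alpha * (reward - q_prev)
}

#' Softmax (logistic) choice probability
#'
#' Probability of choosing deck A given the two deck expectations and the
#' choice-consistency (inverse temperature) parameter `beta`:
#' `P(A) = exp(beta * q_a) / (exp(beta * q_a) + exp(beta * q_b))`,
#' computed overflow-safely. `beta = 0` is indifference; larger `beta` makes
#' choice more deterministic given the expectations.
#'
#' @param q_a,q_b Deck expectations. Vectorized.
#' @param beta Choice consistency, `>= 0`.
#' @return Probability of choosing deck A, in (0, 1).
#' @examples
#' choice_probability(1, 0, 5) # plogis(5)
#' @export
choice_probability <- function(q_a, q_b, beta) {
  if (any(!is.finite(beta)) || any(beta < 0))
    stop("choice consistency `beta` must be non-negative")
  # subtract the max exponent before exponentiating
  m <- pmax(beta * q_a, beta * q_b)
  ea <- exp(beta * q_a - m)
  eb <- exp(beta * q_b - m)
  ea / (ea + eb)
}

#' Simulate one subject on a block schedule
#'
#' Plays a full experimental session: on every trial the agent chooses a deck
#' through the softmax rule on its current expectations, receives independent
#' Bernoulli feedback at the chosen deck's scheduled probability, and updates
#' the chosen deck's expectation by the delta rule. Expectations are not
#' reset at block boundaries (participants are unaware of them).
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Choice consistency, `>= 0`.
#' @param schedule A [make_block_schedule()] result.
#' @param q0 Initial expectation for both decks (default 0.5, the midpoint of
#'   the outcome range).
#' @param seed Optional integer seed; the session is deterministic given it.
#' @param subject_id,condition Labels copied into the trial records.
#' @return A list with `trials` (data frame: subject_id, condition, block,
#'   trial, chosen_deck, deck_class, reward) and `trace` (data frame: q_a,
#'   q_b, p_a per trial, values entering each trial's choice).
#' @examples
#' sched <- make_block_schedule(task_config(), seed = 1)
#' s <- simulate_subject(0.3, 4, sched, seed = 2)
#' head(s$trials)
#' @export
simulate_subject <- function(alpha, beta, schedule, q0 = 0.5, seed = NULL,
                             subject_id = "s1", condition = "neutral") {
  stopifnot(inherits(schedule, "block_schedule"))
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("learning rate `alpha` must lie in [0, 1]")
  if (!is.finite(beta) || beta < 0)
    stop("choice consistency `beta` must be non-negative")
  if (!is.null(seed)) set.seed(as.integer(seed))

  n <- sum(schedule$length)
  block_of <- rep(schedule$block, schedule$length)
  p_a_deck <- rep(schedule$p_a, schedule$length)
  p_b_deck <- rep(schedule$p_b, schedule$length)
  rich <- rep(schedule$rich_deck, schedule$length)

  q <- c(A = q0, B = q0)
  choice <- character(n); reward <- integer(n)
  qa <- numeric(n); qb <- numeric(n); pa <- numeric(n)
  for (t in seq_len(n)) {
    qa[t] <- q[["A"]]; qb[t] <- q[["B"]]
    pa[t] <- choice_probability(q[["A"]], q[["B"]], beta)
    ch <- if (runif(1) < pa[t]) "A" else "B"
    p <- if (ch == "A") p_a_deck[t] else p_b_deck[t]
    rw <- rbinom(1L, 1L, p)
    q[[ch]] <- update_expectation(q[[ch]], rw, alpha)
    choice[t] <- ch; reward[t] <- rw
  }
  trials <- data.frame(
    subject_id = subject_id, condition = condition,
    block = block_of, trial = seq_len(n) - 1L,
    chosen_deck = choice,
    deck_class = ifelse(choice == rich, "rich", "poor"),
    reward = reward)
  trace <- data.frame(q_a = qa, q_b = qb, p_a = pa)
  list(trials = trials, trace = trace)
}
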