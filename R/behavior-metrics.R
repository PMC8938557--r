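#' Classify win-stay/lose-shift strategy events
#'
#' For each trial that has a successor within one subject x condition
#' sequence, records the feedback type (win = rewarded, lose = non-rewarded),
#' the subsequent action (stay = same deck chosen next, shift = other deck),
#' and the deck class (rich/poor) of the feedback trial itself. The last
#' trial has no successor and is excluded. Events are evaluated across block
#' boundaries: the decks persist, only their probabilities shift, and the
#' feedback trial's own block assignment defines its deck class.
#'
#' @param trials Data frame with columns `trial`, `chosen_deck`,
#'   `deck_class`, `reward`, ordered by trial index, from a single
#'   subject x condition.
#' @return Data frame of events with columns `feedback` ("win"/"lose"),
#'   `action` ("stay"/"shift"), `deck_class` ("rich"/"poor").
#' @export
classify_strategy_events <- function(trials) {
  need <- c("trial", "chosen_deck", "deck_class", "reward")
  if (!all(need %in% names(trials)))
    stop("`trials` must have columns trial, chosen_deck, deck_class, reward")
  n <- nrow(trials)
  if (n > 1 && (anyDuplicated(trials$trial) || is.unsorted(trials$trial)))
    stop("trial indices must be strictly increasing without duplicates")
  if (n < 2)
    return(data.frame(feedback = character(), action = character(),
                      deck_class = character()))
  cur <- trials$chosen_deck[-n]
  nxt <- trials$chosen_deck[-1]
  data.frame(
    feedback = ifelse(trials$reward[-n] == 1, "win", "lose"),
    action = ifelse(cur == nxt, "stay", "shift"),
    deck_class = trials$deck_class[-n])
}

#' Win-stay/lose-shift rates from classified events
#'
#' Computes the four strategy rates -- win-stay and lose-shift, each split by
#' rich and poor decks -- together with deck-pooled (event-weighted) overall
#' rates. Each rate is the count of matching (feedback, action) events over
#' the count of matching feedback events. Empty denominators yield `NA`
#' (never 0), so undefined rates drop out of group means instead of biasing
#' them downward. Numerators and denominators are retained.
#'
#' @param events Data frame from [classify_strategy_events()].
#' @return An object of class `strategy_summary`: a list with elements
#'   `win_stay_rich`, `win_stay_poor`, `lose_shift_rich`, `lose_shift_poor`,
#'   `win_stay`, `lose_shift`, each a list `(rate, n, k)` where `k/n` is the
#'   rate (`rate` is `NA` when `n == 0`).
#' @export
strategy_rates <- function(events) {
  rate <- function(fb, act, cls = NULL) {
    sel <- events$feedback == fb
    if (!is.null(cls)) sel <- sel & events$deck_class == cls
    n <- sum(sel)
    k <- sum(sel & events$action == act)
    list(rate = if (n > 0) k / n else NA_real_, n = n, k = k)
  }
  structure(list(
    win_stay_rich = rate("win", "stay", "rich"),
    win_stay_poor = rate("win", "stay", "poor"),
    lose_shift_rich = rate("lose", "shift", "rich"),
    lose_shift_poor = rate("lose", "shift", "poor"),
    win_stay = rate("win", "stay"),
    lose_shift = rate("lose", "shift")),
    class = "strategy_summary")
}

#' @export
print.strategy_summary <- function(x, ...) {
  cat("Win-stay / lose-shift rates:\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf("  %-16s %s  (%d/%d)\n", nm,
                ifelse(is.na(e$rate), "undefined", sprintf("%.3f", e$rate)),
                e$k, e$n))
  }
  invisible(x)
}

#' Total game score
#'
#' Sum of the binary per-trial rewards, the quantity participants are
#' instructed to maximize.
#'
#' @param trials Data frame with a 0/1 `reward` column (or a bare 0/1
#'   vector).
#' @return Integer total points.
#' @export
total_score <- function(trials) {
  r <- if (is.data.frame(trials)) trials$reward else trials
  if (!all(r %in% c(0, 1)))
    stop("rewards must be binary 0/1")
  as.integer(sum(r))
}

#' PANAS post-minus-pre difference scores
#'
#' Mean difference between post-test and pretest ratings on the positive and
#' negative subscales, indexing the subjective change in affect induced
#' during the experimental phase.
#'
#' @param pre,post Numeric vectors of item ratings, same items in the same
#'   order.
#' @param subscale Character vector ("positive"/"negative") labelling each
#'   item.
#' @return A list with `positive_diff` and `negative_diff`.
#' @examples
#' panas_diff(c(2, 3, 4, 1), c(4, 4, 4, 1),
#'            c("positive", "positive", "positive", "negative"))
#' @export
panas_diff <- function(pre, post, subscale) {
  if (length(pre) != length(post) || length(pre) != length(subscale))
    stop("`pre`, `post` and `subscale` must have matching lengths")
  if (!all(subscale %in% c("positive", "negative")))
    stop("subscale labels must be 'positive' or 'negative'")
  d <- post - pre
  list(positive_diff = mean(d[subscale == "positive"]),
       negative_diff = mean(d[subscale == "negative"]))
}

#' Per-subject behavioral summary table
#'
#' Convenience aggregation: computes strategy rates and total score for each
#' subject x condition in a tidy trial table.
#'
#' @param trials Data frame in the [simulate_subject()] trial schema,
#'   possibly covering many subjects and conditions.
#' @return Data frame, one row per subject x condition, with the four
#'   class-split rates, the two pooled rates, event counts and total score.
#' @export
behavior_summary <- function(trials) {
  split_by <- interaction(trials$subject_id, trials$condition, drop = TRUE)
  rows <- lapply(split(trials, split_by), function(tt) {
    tt <- tt[order(tt$trial), ]
    s <- strategy_rates(classify_strategy_events(tt))
    data.frame(
      subject_id = tt$subject_id[1], condition = tt$condition[1],
      win_stay_rich = s$win_stay_rich$rate,
      win_stay_poor = s$win_stay_poor$rate,
      lose_shift_rich = s$lose_shift_rich$rate,
      lose_shift_poor = s$lose_shift_poor$rate,
      win_stay = s$win_stay$rate,
      lose_shift = s$lose_shift$rate,
      n_win = s$win_stay$n, n_lose = s$lose_shift$n,
      total_score = total_score(tt))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
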