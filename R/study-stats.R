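#' Pearson correlation with a two-sided p value
#'
#' Product-moment correlation; the p value comes from the t transform
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom (via
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `>= 3` with non-zero
#'   variance; pairs with missing values are dropped.
#' @return List with `r`, `p`, and `n` (complete pairs used).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Holm-Bonferroni sequential correction
#'
#' Step-down adjustment: with the `m` p values sorted ascending, the k-th
#' adjusted value is `max_{j<=k} (m-j+1) p_(j)`, capped at 1; hypotheses are
#' rejected sequentially while the adjusted value stays at or below `alpha`.
#' Results are returned in input order.
#'
#' @param p Numeric vector of p values in (0, 1].
#' @param alpha Family-wise error level.
#' @return List with `adjusted` (adjusted p values) and `reject` (logical
#'   flags).
#' @examples
#' holm_bonferroni(c(0.01, 0.04))   # both rejected at 0.05
#' holm_bonferroni(c(0.03, 0.10))   # neither rejected
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p values must lie in (0, 1]")
  adj <- p.adjust(p, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Correlation table between task measures and symptom factors
#'
#' Builds the measure x condition x factor grid of Pearson correlations in
#' the patient group, with Holm-Bonferroni correction applied within
#' configurable families. The default family pools, per measurement type,
#' the 3 conditions x 5 factors = 15 tests. Missing subjects are dropped
#' pairwise; complete-pair counts are reported per cell.
#'
#' @param measures Long data frame: `subject_id`, `condition`, `measure`,
#'   `value`.
#' @param symptoms Data frame: `subject_id` plus one column per factor.
#' @param family How cells share a Holm family: `"measure"` (default, all
#'   conditions and factors of one measurement type), `"measure_condition"`
#'   (each table row), or `"all"` (one family).
#' @param alpha Significance level.
#' @return Data frame of class `correlation_table`, one row per cell:
#'   `measure`, `condition`, `factor`, `r`, `p`, `n`, `p_holm`,
#'   `sig_raw`, `sig_holm`. Cells with fewer than 3 complete pairs are
#'   flagged `unavailable` with `NA` statistics.
#' @export
correlation_table <- function(measures, symptoms,
                              family = c("measure", "measure_condition",
                                         "all"),
                              alpha = 0.05) {
  family <- match.arg(family)
  need <- c("subject_id", "condition", "measure", "value")
  if (!all(need %in% names(measures)))
    stop("`measures` must have columns subject_id, condition, measure, value")
  factors <- setdiff(names(symptoms), "subject_id")
  rows <- list()
  for (m in unique(measures$measure)) {
    for (cond in unique(measures$condition)) {
      mm <- measures[measures$measure == m & measures$condition == cond, ]
      merged <- merge(mm, symptoms, by = "subject_id")
      for (f in factors) {
        x <- merged$value; y <- merged[[f]]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) >= 3L && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
          pr <- pearson_r(x[ok], y[ok])
          rows[[length(rows) + 1L]] <- data.frame(
            measure = m, condition = cond, factor = f,
            r = pr$r, p = pr$p, n = pr$n, unavailable = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            measure = m, condition = cond, factor = f,
            r = NA_real_, p = NA_real_, n = sum(ok), unavailable = TRUE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  fam <- switch(family,
                measure = out$measure,
                measure_condition = paste(out$measure, out$condition),
                all = rep("all", nrow(out)))
  out$p_holm <- NA_real_
  for (f in unique(fam)) {
    sel <- fam == f & !is.na(out$p)
    if (any(sel))
      out$p_holm[sel] <- holm_bonferroni(out$p[sel], alpha)$adjusted
  }
  out$sig_raw <- !is.na(out$p) & out$p <= alpha
  out$sig_holm <- !is.na(out$p_holm) & out$p_holm <= alpha
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("Correlations between task measures and symptom factors\n")
  df <- as.data.frame(x)
  df$r <- round(df$r, 3); df$p <- round(df$p, 3)
  df$p_holm <- round(df$p_holm, 3)
  print(df[, c("measure", "condition", "factor", "r", "p", "p_holm",
               "sig_raw", "sig_holm")], row.names = FALSE)
  invisible(x)
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates: cohort generation, behavioral summaries (scores and
#' win-stay/lose-shift), per group x condition hierarchical model fits,
#' ERP extraction across the cohort, and the patient correlation table.
#' Stage timings are logged to standard error.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for the whole run.
#' @param mcmc An [mcmc_config()] used for every group x condition fit;
#'   set `fit = FALSE` to skip model fitting (true parameters are then used
#'   in the correlation table).
#' @param fit Run the MCMC fits (default `TRUE`).
#' @param eeg Run EEG synthesis + ERP extraction (default taken from
#'   `config$eeg$enabled`); when skipped, true template amplitudes are used
#'   downstream.
#' @param holm_family Passed to [correlation_table()].
#' @return An object of class `study_report`: list with `study`,
#'   `behavior` (per subject x condition), `group_behavior` (group x
#'   condition means), `fits` (list of `rlhb` objects, when run),
#'   `model_params` (per-subject posterior means or truth), `erp`
#'   (per-subject measures), `group_erp`, `panas`, `correlations`, `seed`.
#' @export
run_study <- function(config = cohort_config(), seed = 1,
                      mcmc = mcmc_config("fast"), fit = TRUE,
                      eeg = NULL, holm_family = "measure") {
  t0 <- proc.time()[3]
  stage <- function(what) message(sprintf("[run_study] %-22s %6.1f s",
                                          what, proc.time()[3] - t0))
  study <- generate_cohort(config, seed)
  stage("cohort generated")

  behavior <- merge(behavior_summary(study$trials),
                    study$roster, by = "subject_id")
  num <- c("win_stay_rich", "win_stay_poor", "lose_shift_rich",
           "lose_shift_poor", "win_stay", "lose_shift", "total_score")
  group_behavior <- aggregate(behavior[num],
                              by = list(group = behavior$group,
                                        condition = behavior$condition),
                              FUN = mean, na.rm = TRUE)
  stage("behavior summarized")

  fits <- list(); model_params <- NULL
  if (fit) {
    for (g in unique(study$roster$group)) {
      ids <- study$roster$subject_id[study$roster$group == g]
      for (cond in config$conditions) {
        tt <- study$trials[study$trials$subject_id %in% ids &
                             study$trials$condition == cond, ]
        key <- paste(g, cond, sep = ".")
        f <- fit_rlhb(tt, config = mcmc, q0 = config$q0,
                      seed = sample.int(.Machine$integer.max, 1))
        fits[[key]] <- f
        est <- coef(f, "subject")
        est$group <- g; est$condition <- cond
        model_params <- rbind(model_params, est)
        stage(sprintf("fit %s", key))
      }
    }
  } else {
    model_params <- study$params[, c("subject_id", "alpha", "beta",
                                     "group", "condition")]
  }

  if (is.null(eeg)) eeg <- isTRUE(config$eeg$enabled)
  erp <- NULL; group_erp <- NULL
  if (eeg) {
    erp <- cohort_erp_measures(study)
    group_erp <- aggregate(erp[c("n170", "p200", "frn")],
                           by = list(group = erp$group,
                                     condition = erp$condition),
                           FUN = mean, na.rm = TRUE)
    stage("ERP extracted")
  }

  sz_ids <- study$roster$subject_id[study$roster$group == "SZ"]
  mp <- model_params[model_params$subject_id %in% sz_ids, ]
  meas <- rbind(
    data.frame(subject_id = mp$subject_id, condition = mp$condition,
               measure = "learning_rate", value = mp$alpha),
    data.frame(subject_id = mp$subject_id, condition = mp$condition,
               measure = "choice_consistency", value = mp$beta))
  if (eeg) {
    esz <- erp[erp$subject_id %in% sz_ids, ]
    meas <- rbind(meas,
      data.frame(subject_id = esz$subject_id, condition = esz$condition,
                 measure = "P200", value = esz$p200),
      data.frame(subject_id = esz$subject_id, condition = esz$condition,
                 measure = "FRN", value = esz$frn))
  } else {
    psz <- study$params[study$params$subject_id %in% sz_ids, ]
    meas <- rbind(meas,
      data.frame(subject_id = psz$subject_id, condition = psz$condition,
                 measure = "P200", value = psz$p200),
      data.frame(subject_id = psz$subject_id, condition = psz$condition,
                 measure = "FRN", value = psz$frn))
  }
  correlations <- correlation_table(meas, study$symptoms,
                                    family = holm_family)
  stage("correlations")

  structure(list(study = study, behavior = behavior,
                 group_behavior = group_behavior, fits = fits,
                 model_params = model_params, erp = erp,
                 group_erp = group_erp, panas = study$panas,
                 correlations = correlations, seed = as.integer(seed)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic study report (seed", x$seed, ")\n\n")
  cat("Group x condition behavior (means):\n")
  gb <- x$group_behavior
  gb[, -(1:2)] <- round(gb[, -(1:2)], 3)
  print(gb, row.names = FALSE)
  if (!is.null(x$group_erp)) {
    cat("\nGroup x condition ERP amplitudes (uV):\n")
    ge <- x$group_erp
    ge[, -(1:2)] <- round(ge[, -(1:2)], 2)
    print(ge, row.names = FALSE)
  }
  cat("\nHolm-significant correlation cells:\n")
  sig <- x$correlations[x$correlations$sig_holm, , drop = FALSE]
  if (nrow(sig)) print(as.data.frame(sig)[, 1:5], row.names = FALSE)
  else cat("  (none)\n")
  invisible(x)
}
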