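#' Win-stay / lose-shift proportions
#'
#' For each trial after the first, "stay" means repeating the previous
#' trial's choice (by car identity, not screen side). Proportions are
#' conditioned on the previous trial's outcome (win/loss) and on whether
#' the previously chosen car was the high- or low-probability car under the
#' contingency in force on that trial.
#'
#' @param session Session tibble with `best_car`, `choice`, `outcome`.
#'
#' @return A tibble with columns `car_class` (`"high_prob"`/`"low_prob"`),
#'   `stay_after_win`, `stay_after_loss` (proportions in `[0, 1]`, `NA`
#'   when a conditioning cell is empty), `n_win`, `n_loss`.
#' @export
win_stay_lose_shift <- function(session) {
  n <- nrow(session)
  if (n < 2L) stop("need at least 2 trials", call. = FALSE)
  prev <- seq_len(n - 1L)
  cur <- prev + 1L
  stay <- session$choice[cur] == session$choice[prev]
  prev_win <- session$outcome[prev] == 1
  prev_class <- ifelse(session$choice[prev] == session$best_car[prev],
                       "high_prob", "low_prob")
  purrr::map_dfr(c("high_prob", "low_prob"), function(cl) {
    w <- prev_class == cl & prev_win
    l <- prev_class == cl & !prev_win
    tibble::tibble(
      car_class = cl,
      stay_after_win = if (any(w)) mean(stay[w]) else NA_real_,
      stay_after_loss = if (any(l)) mean(stay[l]) else NA_real_,
      n_win = sum(w), n_loss = sum(l)
    )
  })
}

#' Per-session behavioural summary
#'
#' Choice accuracy is the proportion of trials on which the option with the
#' higher objective expected value (objective win probability times offered
#' reward) was chosen; trials where the two expected values tie are
#' excluded from the denominator. The high-probability choice rate uses the
#' contingency of the current block.
#'
#' @param session Session tibble.
#'
#' @return One-row tibble with `accuracy`, `p_high_prob_choice`,
#'   `p_win` (obtained win rate), `mean_happiness`, `sd_happiness`,
#'   `n_ratings`.
#' @export
behaviour_summary <- function(session) {
  # both probabilities written directly so EV ties are exact in floating
  # point (1 - 0.8 != 0.2 exactly) and the metric is label-symmetric
  p_A <- ifelse(session$best_car == "A", 0.8, 0.2)
  p_B <- ifelse(session$best_car == "B", 0.8, 0.2)
  ev_A <- p_A * session$reward_A
  ev_B <- p_B * session$reward_B
  untied <- ev_A != ev_B
  best_ev <- ifelse(ev_A > ev_B, "A", "B")
  ratings <- session$rating[session$is_rating_trial &
                              !is.na(session$rating)]
  tibble::tibble(
    accuracy = mean((session$choice == best_ev)[untied]),
    p_high_prob_choice = mean(session$choice == session$best_car),
    p_win = mean(session$outcome),
    mean_happiness = if (length(ratings)) mean(ratings) else NA_real_,
    sd_happiness = if (length(ratings) > 1) stats::sd(ratings) else
      NA_real_,
    n_ratings = length(ratings)
  )
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Paired signed-rank test reporting the normal-approximation z statistic
#' (tie-corrected, with continuity correction), as used for group-level
#' comparisons of paired per-subject quantities. Zero differences are
#' dropped. For fewer than 20 non-zero differences without ties the exact
#' signed-rank distribution supplies the p-value; otherwise the normal
#' approximation is used.
#'
#' @param x,y Paired numeric vectors, or a single vector of differences if
#'   `y` is `NULL`.
#'
#' @return One-row tibble with `v` (signed-rank statistic), `z`, `p`, `n`
#'   (non-zero pairs).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) stop("all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  cc <- sign(v - mu) * 0.5
  z <- if (sigma2 > 0) (v - mu - cc) / sqrt(sigma2) else 0
  has_ties <- any(duplicated(abs(d)))
  p <- if (n < 20 && !has_ties) {
    p_low <- stats::psignrank(v, n)
    p_high <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    min(1, 2 * min(p_low, p_high))
  } else {
    2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(v = v, z = z, p = p, n = n)
}

#' Spearman rank correlation
#'
#' Tie-handling rank correlation with the asymptotic t-approximation
#' p-value, as used for cross-subject associations.
#'
#' @param x,y Numeric vectors.
#'
#' @return One-row tibble with `rho`, `p`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Standardised-difference correlation with a symptom score
#'
#' Z-standardises a per-subject quantity within each environment, takes the
#' volatile-minus-stable difference, and rank-correlates it with the
#' standardised symptom score. Used to ask whether depressive symptoms
#' relate more strongly to mood in the volatile than the stable
#' environment.
#'
#' @param stable,volatile Per-subject values in the two environments.
#' @param symptom Per-subject symptom scores (e.g. PHQ 0-27).
#'
#' @return One-row tibble with `rho`, `p`, `n`.
#' @export
standardized_difference_correlation <- function(stable, volatile,
                                                symptom) {
  ok <- stats::complete.cases(stable, volatile, symptom)
  stable <- stable[ok]
  volatile <- volatile[ok]
  symptom <- symptom[ok]
  if (stats::sd(stable) == 0 || stats::sd(volatile) == 0) {
    stop("constant condition values: standardised difference undefined",
         call. = FALSE)
  }
  d <- as.numeric(scale(volatile)) - as.numeric(scale(stable))
  if (stats::sd(d) == 0) {
    stop("identical standardised conditions: difference is constant",
         call. = FALSE)
  }
  spearman(d, as.numeric(scale(symptom)))
}

#' Lagged probability-prediction-error regression
#'
#' Model-free check on the happiness forgetting factor: regresses each
#' rating on the `n_lags` most recent subjective PPEs (lag 1 = the trial
#' the rating follows). Only ratings with at least `n_lags` preceding
#' trials enter.
#'
#' @param session Session tibble.
#' @param terms Term history from [build_term_history()].
#' @param n_lags Number of lags (default 10).
#' @param zscore Standardise the ratings first (default `TRUE`).
#'
#' @return A tibble with `lag` and `estimate` (OLS coefficient per lag);
#'   `NA` estimates with a warning if the design is rank deficient.
#' @export
lagged_ppe_regression <- function(session, terms, n_lags = 10,
                                  zscore = TRUE) {
  rating_trials <- which(session$is_rating_trial & !is.na(session$rating))
  rating_trials <- rating_trials[rating_trials >= n_lags]
  if (length(rating_trials) <= n_lags + 1L) {
    stop("not enough ratings with ", n_lags, " preceding trials",
         call. = FALSE)
  }
  y <- session$rating[rating_trials]
  if (zscore) y <- as.numeric(scale(y))
  X <- vapply(seq_len(n_lags), function(l) {
    terms$ppe_hat[rating_trials - l + 1L]
  }, numeric(length(rating_trials)))
  colnames(X) <- paste0("lag", seq_len(n_lags))
  fit <- stats::lm.fit(cbind(1, X), y)
  coefs <- fit$coefficients[-1]
  if (anyNA(coefs)) warning("rank-deficient lag design; NA coefficients")
  tibble::tibble(lag = seq_len(n_lags), estimate = unname(coefs))
}

#' Residual correlation of the win-loss model with probability estimates
#'
#' Computes the rating-trial residuals of a fitted win-loss happiness model
#' and rank-correlates them with the trial-by-trial chosen-probability
#' estimate. A negative correlation indicates an influence of probability
#' estimates on happiness beyond the win/loss history.
#'
#' @param session Session tibble.
#' @param winloss_fit A `happiness_fit` for model `"winloss"` on this
#'   session.
#' @param terms Term history from [build_term_history()].
#'
#' @return One-row tibble with `rho`, `p`, `n`.
#' @export
winloss_residual_probability_correlation <- function(session, winloss_fit,
                                                     terms) {
  stopifnot(inherits(winloss_fit, "happiness_fit"),
            identical(winloss_fit$model, "winloss"))
  if (!identical(winloss_fit$flag, "ok") &&
      !identical(winloss_fit$flag, "flat_gamma")) {
    stop("win-loss fit is flagged '", winloss_fit$flag, "'", call. = FALSE)
  }
  resid <- winloss_fit$observed - winloss_fit$predicted
  p_hat <- terms$p_hat_chosen[winloss_fit$rating_trials]
  spearman(resid, p_hat)
}

#' Group-level summary tables for a fitted cohort
#'
#' Convenience wrapper producing the per-environment group means (± SEM)
#' of behavioural metrics and fitted parameters, with paired signed-rank
#' comparisons between environments.
#'
#' @param per_subject Tibble with one row per subject x environment and
#'   numeric metric columns.
#' @param metrics Character vector of metric column names to summarise.
#'
#' @return A tibble with `metric`, per-environment `mean` and `sem`, and
#'   the paired `z`/`p` for volatile minus stable (subjects present in both
#'   environments).
#' @export
group_environment_table <- function(per_subject, metrics) {
  purrr::map_dfr(metrics, function(m) {
    wide <- tidyr::pivot_wider(
      per_subject[, c("subject", "environment", m)],
      names_from = "environment", values_from = dplyr::all_of(m)
    )
    ok <- stats::complete.cases(wide$stable, wide$volatile)
    wt <- tryCatch(
      wilcoxon_signed_rank(wide$volatile[ok], wide$stable[ok]),
      error = function(e) tibble::tibble(v = NA, z = NA, p = NA, n = 0)
    )
    sem <- function(v) stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    tibble::tibble(
      metric = m,
      stable_mean = mean(wide$stable, na.rm = TRUE),
      stable_sem = sem(wide$stable),
      volatile_mean = mean(wide$volatile, na.rm = TRUE),
      volatile_sem = sem(wide$volatile),
      z = wt$z, p = wt$p, n = wt$n
    )
  })
}
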