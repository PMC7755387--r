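#' The momentary-happiness model family
#'
#' Eleven regression models of momentary happiness, each a baseline plus a
#' weighted sum of exponentially decaying trial histories with a shared
#' forgetting factor `gamma`:
#' \deqn{Happiness(t) = w_0 + \sum_{terms} w \sum_{j=1}^{t} \gamma^{t-j} x_j.}
#' Histories run over all completed trials; a rating is attributed to the
#' most recent trial whose outcome has been seen.
#'
#' Model ids and their history terms (parameter counts include `w0` and
#' `gamma`; the Gaussian noise scale is profiled out and not counted):
#'
#' * `ppe_hat` (k=3): subjective probability prediction errors.
#' * `rpe_hat` (k=3): subjective reward prediction errors.
#' * `ppe_obj` (k=3): objective PPEs (true 0.2/0.8 contingencies).
#' * `rpe_obj` (k=3): objective RPEs.
#' * `p_ppe` (k=4): chosen-probability estimate (centred at 0.5) + subjective
#'   PPEs.
#' * `ev_ppe` (k=4): mean-centred expected value + subjective PPEs.
#' * `ev_rpe` (k=4): mean-centred expected value + subjective RPEs.
#' * `p_rpe` (k=4): chosen probability + subjective RPEs.
#' * `r_mean` (k=3): obtained reward relative to its session mean.
#' * `r_rp` (k=4): obtained reward relative to a fitted reference point `RP`
#'   in `[0, 80]` points.
#' * `winloss` (k=4): `+ w_win` on the win history and `- w_loss` on the
#'   loss history.
#'
#' @return `happiness_models()` returns a tibble with columns `model`,
#'   `terms` (list column) and `k`.
#' @export
happiness_models <- function() {
  reg <- hm_registry()
  tibble::tibble(
    model = names(reg),
    terms = unname(purrr::map(reg, "terms")),
    k = unname(purrr::map_int(reg, "k"))
  )
}

hm_registry <- function() {
  list(
    ppe_hat = list(terms = "ppe_hat", k = 3L, special = "none"),
    rpe_hat = list(terms = "rpe_hat", k = 3L, special = "none"),
    ppe_obj = list(terms = "ppe_obj", k = 3L, special = "none"),
    rpe_obj = list(terms = "rpe_obj", k = 3L, special = "none"),
    p_ppe = list(terms = c("p_hat_centered", "ppe_hat"), k = 4L,
                 special = "none"),
    ev_ppe = list(terms = c("ev_hat_centered", "ppe_hat"), k = 4L,
                  special = "none"),
    ev_rpe = list(terms = c("ev_hat_centered", "rpe_hat"), k = 4L,
                  special = "none"),
    p_rpe = list(terms = c("p_hat_centered", "rpe_hat"), k = 4L,
                 special = "none"),
    r_mean = list(terms = "r_centered", k = 3L, special = "none"),
    r_rp = list(terms = "r_points", k = 4L, special = "rp"),
    winloss = list(terms = c("win_flag", "loss_flag"), k = 4L,
                   special = "winloss")
  )
}

hm_model <- function(model) {
  reg <- hm_registry()
  if (!model %in% names(reg)) {
    stop("unknown happiness model: '", model, "'. See happiness_models().",
         call. = FALSE)
  }
  reg[[model]]
}

#' Build the per-trial history terms for the happiness models
#'
#' Replays the Rescorla-Wagner learner at a given (usually fitted) learning
#' rate to obtain the subjective chosen-probability estimate on every trial,
#' then derives all history terms used by the model family. Objective terms
#' use the scheduled 0.8/0.2 contingency of the chosen car. Rewards inside
#' prediction-error terms are rescaled to `[0, 1]` by `max_reward`; the
#' reward-history terms (`r_*`) stay in points so the reference point is in
#' points.
#'
#' @param session A session tibble (simulated or imported) with `winner`,
#'   `best_car`, `choice`, `outcome`, `reward_A`, `reward_B`,
#'   `obtained_points`.
#' @param choice_fit Either a `choice_fit` from the additive model or a bare
#'   learning rate in `[0, 1]`.
#' @param max_reward Reward normaliser (default 80).
#'
#' @return A tibble, one row per trial, with columns `trial`,
#'   `p_hat_chosen`, `ppe_hat`, `rpe_hat`, `ppe_obj`, `rpe_obj`,
#'   `p_hat_centered`, `ev_hat_centered`, `r_points`, `r_centered`,
#'   `win_flag`, `loss_flag`.
#' @export
build_term_history <- function(session, choice_fit, max_reward = 80) {
  alpha <- if (inherits(choice_fit, "choice_fit")) {
    if (!"alpha" %in% names(choice_fit$par)) {
      stop("`choice_fit` has no learning rate; use an additive-family fit.",
           call. = FALSE)
    }
    unname(choice_fit$par["alpha"])
  } else {
    as.numeric(choice_fit)
  }
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1].",
                                   call. = FALSE)
  beliefs <- replay_beliefs(session$winner, alpha)
  chose_A <- session$choice == "A"
  p_hat <- ifelse(chose_A, beliefs$p_A, 1 - beliefs$p_A)
  outcome <- session$outcome
  reward_chosen <- ifelse(chose_A, session$reward_A, session$reward_B)
  r_scaled <- session$obtained_points / max_reward
  ev_hat <- p_hat * reward_chosen / max_reward
  p_obj <- ifelse(session$choice == session$best_car, 0.8, 0.2)
  ev_obj <- p_obj * reward_chosen / max_reward

  tibble::tibble(
    trial = session$trial,
    p_hat_chosen = p_hat,
    ppe_hat = outcome - p_hat,
    rpe_hat = r_scaled - ev_hat,
    ppe_obj = outcome - p_obj,
    rpe_obj = r_scaled - ev_obj,
    p_hat_centered = p_hat - 0.5,
    ev_hat_centered = ev_hat - mean(ev_hat),
    r_points = as.numeric(session$obtained_points),
    r_centered = session$obtained_points - mean(session$obtained_points),
    win_flag = as.numeric(outcome),
    loss_flag = 1 - outcome
  )
}

#' Exponentially decaying sum of a trial history
#'
#' `decayed_sum()` returns \eqn{\sum_{j=1}^{t} \gamma^{t-j} x_j};
#' `decayed_trace()` returns that quantity for every `t` at once, computed
#' by the recursion \eqn{S_t = \gamma S_{t-1} + x_t}.
#'
#' @param series Numeric per-trial values.
#' @param gamma Forgetting factor in `[0, 1]`; 0 keeps only the current
#'   trial, 1 weights all past trials equally.
#' @param t Trial index (default: the last trial).
#'
#' @return A scalar (`decayed_sum`) or a vector the length of `series`
#'   (`decayed_trace`).
#' @export
#' @examples
#' decayed_sum(c(1, 0, 1), gamma = 0.5)  # 1.25
decayed_sum <- function(series, gamma, t = length(series)) {
  stopifnot(t >= 1, gamma >= 0, gamma <= 1)
  decayed_trace(series[seq_len(t)], gamma)[t]
}

#' @rdname decayed_sum
#' @export
decayed_trace <- function(series, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  n <- length(series)
  out <- numeric(n)
  cur <- 0
  for (j in seq_len(n)) {
    cur <- gamma * cur + series[j]
    out[j] <- cur
  }
  out
}

#' Happiness-model parameter sets
#'
#' @param model Model id; see [happiness_models()].
#' @param w0 Baseline term (0 on the z-scored scale; rating units in
#'   `[0, 100]` for raw fits).
#' @param weights Named numeric vector of term weights. Names follow the
#'   model's term columns (e.g. `p_hat_centered`, `ppe_hat`; `win_flag` /
#'   `loss_flag` hold `w_win` / `w_loss`, both entering with the
#'   `+win - loss` sign convention).
#' @param gamma Forgetting factor in `[0, 1]`.
#' @param rp Reference point in points (model `r_rp` only).
#'
#' @return A list of class `happiness_params`.
#' @export
#' @examples
#' happiness_params("p_ppe",
#'                  weights = c(p_hat_centered = 0.74, ppe_hat = 1.32),
#'                  gamma = 0.59)
happiness_params <- function(model, w0 = 0, weights, gamma, rp = NULL) {
  spec <- hm_model(model)
  if (gamma < 0 || gamma > 1) stop("`gamma` must lie in [0, 1].",
                                   call. = FALSE)
  if (!setequal(names(weights), spec$terms)) {
    stop("`weights` must be named exactly: ",
         paste(spec$terms, collapse = ", "), call. = FALSE)
  }
  if (identical(spec$special, "rp") && is.null(rp)) {
    stop("model 'r_rp' requires `rp`.", call. = FALSE)
  }
  structure(list(model = model, w0 = w0,
                 weights = weights[spec$terms], gamma = gamma, rp = rp),
            class = "happiness_params")
}

# decayed regressor matrix for a model at a given gamma, evaluated on all
# trials; special handling expands the r_rp model into the linear pair
# (D(reward), D(1)) so the reference point can be profiled by OLS
hm_design <- function(model_spec, terms, gamma) {
  block <- if (".block" %in% names(terms)) terms$.block else
    rep(1L, nrow(terms))
  trace_by_block <- function(x) {
    out <- numeric(length(x))
    for (b in unique(block)) {
      idx <- which(block == b)
      out[idx] <- decayed_trace(x[idx], gamma)
    }
    out
  }
  cols <- lapply(model_spec$terms, function(tm) trace_by_block(terms[[tm]]))
  X <- do.call(cbind, cols)
  colnames(X) <- model_spec$terms
  if (identical(model_spec$special, "rp")) {
    X <- cbind(X, ones = trace_by_block(rep(1, nrow(terms))))
  }
  X
}

#' Predict happiness ratings from a parameter set
#'
#' Evaluates the model equation at the requested rating trials, using the
#' decayed history over all trials `1..t`.
#'
#' @param params A [happiness_params()].
#' @param terms Term history from [build_term_history()].
#' @param rating_trials Integer trial indices of the ratings.
#'
#' @return Numeric vector of predicted happiness, one per rating trial.
#' @export
predict_happiness <- function(params, terms, rating_trials) {
  stopifnot(inherits(params, "happiness_params"))
  spec <- hm_model(params$model)
  w <- params$weights
  pred_all <- rep(params$w0, nrow(terms))
  if (identical(spec$special, "rp")) {
    base <- terms$r_points - params$rp
    pred_all <- pred_all +
      w[["r_points"]] * decayed_trace(base, params$gamma)
  } else if (identical(spec$special, "winloss")) {
    pred_all <- pred_all +
      w[["win_flag"]] * decayed_trace(terms$win_flag, params$gamma) -
      w[["loss_flag"]] * decayed_trace(terms$loss_flag, params$gamma)
  } else {
    for (tm in spec$terms) {
      pred_all <- pred_all + w[[tm]] * decayed_trace(terms[[tm]],
                                                     params$gamma)
    }
  }
  pred_all[rating_trials]
}

# weights + RSS at a fixed gamma by ordinary least squares;
# returns list(coef, rss, pred) with coef in design-column order
hm_ols <- function(y, X, intercept = TRUE) {
  Xf <- if (intercept) cbind(`(w0)` = 1, X) else X
  fit <- stats::lm.fit(Xf, y)
  pred <- y - fit$residuals
  list(coef = fit$coefficients, rss = sum(fit$residuals^2), pred = pred)
}

hm_rss_at_gamma <- function(gamma, y, terms, model_spec) {
  X <- hm_design(model_spec, terms, gamma)[attr(y, "rating_trials"), ,
                                           drop = FALSE]
  hm_ols(y, X)$rss
}

#' Fit a momentary-happiness model to one session
#'
#' Gaussian maximum likelihood with the linear weights profiled out: for
#' each candidate forgetting factor the weights (and, for `r_rp`, the
#' reference point via the linear reparameterisation
#' `w * D(R) - (w * RP) * D(1)`) are solved by ordinary least squares, and
#' `gamma` is optimised over `[0, 1]` by a dense grid plus local
#' refinement. The noise variance is concentrated out of the likelihood and
#' not counted as a parameter, so `k` matches the model family's parameter
#' counts.
#'
#' @param session Session tibble carrying a `rating` column (`NA` off
#'   rating trials) and `is_rating_trial`.
#' @param terms Term history from [build_term_history()].
#' @param model Model id; see [happiness_models()].
#' @param zscore If `TRUE` (default), ratings are standardised within the
#'   session before fitting, as when comparing subjects who use the rating
#'   scale differently. If `FALSE`, ratings are fitted on their native scale
#'   and the baseline is constrained to `[0, 100]` when ratings are on the
#'   0-100 scale.
#' @param gamma_grid_step Grid step for the forgetting-factor profile
#'   (default 0.01).
#' @param init Optional [happiness_params()] (e.g. from a joint fit across
#'   environments) whose `gamma` seeds an extra local refinement.
#' @param w0_bounds Optional bounds for the baseline, e.g. `c(0, 100)` when
#'   fitting raw 0-100 ratings (`NULL`, the default, leaves the baseline
#'   unconstrained; ignored when `zscore = TRUE`).
#'
#' @return An object of class `happiness_fit`: `par`
#'   (a [happiness_params()]), `weights`, `gamma`, `rp`, `w0`, `logLik`,
#'   `bic`, `r2` (squared correlation of predicted and observed ratings),
#'   `r2_ve` (variance explained, `1 - RSS/TSS`), `n_ratings`, `model`,
#'   `k`, `flag` (`"ok"`, `"degenerate"` or `"flat_gamma"`), plus
#'   `observed`, `predicted` and `rating_trials` for diagnostics.
#' @export
fit_happiness_model <- function(session, terms, model, zscore = TRUE,
                                gamma_grid_step = 0.01, init = NULL,
                                w0_bounds = NULL) {
  spec <- hm_model(model)
  rating_trials <- which(session$is_rating_trial & !is.na(session$rating))
  if (length(rating_trials) < 5L) {
    stop("need at least 5 ratings to fit a happiness model", call. = FALSE)
  }
  y_raw <- session$rating[rating_trials]
  if (stats::sd(y_raw) == 0) {
    return(hm_flagged_fit(model, spec, length(rating_trials), "degenerate"))
  }
  y <- if (zscore) as.numeric(scale(y_raw)) else y_raw
  attr(y, "rating_trials") <- rating_trials

  grid <- seq(0, 1, by = gamma_grid_step)
  rss_grid <- vapply(grid, hm_rss_at_gamma, numeric(1),
                     y = y, terms = terms, model_spec = spec)
  i_best <- which.min(rss_grid)
  lo <- max(grid[i_best] - gamma_grid_step, 0)
  hi <- min(grid[i_best] + gamma_grid_step, 1)
  opt <- stats::optimize(hm_rss_at_gamma, c(lo, hi), y = y, terms = terms,
                         model_spec = spec, tol = 1e-8)
  gamma <- opt$minimum
  rss <- opt$objective
  if (rss_grid[i_best] < rss) {
    gamma <- grid[i_best]
    rss <- rss_grid[i_best]
  }
  if (!is.null(init) && inherits(init, "happiness_params")) {
    lo2 <- max(init$gamma - 0.05, 0)
    hi2 <- min(init$gamma + 0.05, 1)
    opt2 <- stats::optimize(hm_rss_at_gamma, c(lo2, hi2), y = y,
                            terms = terms, model_spec = spec, tol = 1e-8)
    if (opt2$objective < rss) {
      gamma <- opt2$minimum
      rss <- opt2$objective
    }
  }

  # gamma identifiability: a flat RSS profile means the data do not
  # constrain the forgetting factor (e.g. pure-noise ratings)
  flat <- (max(rss_grid) - min(rss_grid)) < 1e-3 * stats::var(y) *
    length(y)

  X <- hm_design(spec, terms, gamma)[rating_trials, , drop = FALSE]
  sol <- hm_ols(y, X)
  coefs <- sol$coef
  w0 <- unname(coefs["(w0)"])
  pred <- sol$pred

  rp <- NULL
  if (identical(spec$special, "rp")) {
    a <- unname(coefs["r_points"])
    b <- unname(coefs["ones"])
    rp <- if (abs(a) < 1e-10) 0 else -b / a
    if (rp < 0 || rp > 80) {
      rp <- min(max(rp, 0), 80)
      Xc <- matrix(decayed_trace(terms$r_points - rp, gamma)[rating_trials],
                   ncol = 1, dimnames = list(NULL, "r_points"))
      sol <- hm_ols(y, Xc)
      coefs <- sol$coef
      w0 <- unname(coefs["(w0)"])
      pred <- sol$pred
      rss <- sum((y - pred)^2)
    }
    weights <- c(r_points = unname(coefs["r_points"]))
  } else if (identical(spec$special, "winloss")) {
    weights <- c(win_flag = unname(coefs["win_flag"]),
                 loss_flag = -unname(coefs["loss_flag"]))
  } else {
    weights <- stats::setNames(unname(coefs[spec$terms]), spec$terms)
  }

  # raw-rating fits: keep the baseline inside the rating scale
  if (!zscore && !is.null(w0_bounds) &&
      (w0 < w0_bounds[1] || w0 > w0_bounds[2])) {
    w0 <- min(max(w0, w0_bounds[1]), w0_bounds[2])
    Xo <- X
    solo <- hm_ols(y - w0, Xo, intercept = FALSE)
    coefs <- solo$coef
    pred <- solo$pred + w0
    rss <- sum((y - pred)^2)
    if (identical(spec$special, "winloss")) {
      weights <- c(win_flag = unname(coefs["win_flag"]),
                   loss_flag = -unname(coefs["loss_flag"]))
    } else if (!identical(spec$special, "rp")) {
      weights <- stats::setNames(unname(coefs[spec$terms]), spec$terms)
    }
  }

  n <- length(y)
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  k <- spec$k
  r2 <- if (stats::sd(pred) > 0) stats::cor(pred, y)^2 else 0
  par <- happiness_params(model, w0 = w0, weights = weights, gamma = gamma,
                          rp = rp)
  structure(
    list(
      par = par, weights = weights, gamma = gamma, rp = rp, w0 = w0,
      logLik = ll, bic = k * log(n) - 2 * ll, r2 = r2,
      r2_ve = 1 - rss / sum((y - mean(y))^2), n_ratings = n, model = model,
      k = k, flag = if (flat) "flat_gamma" else "ok", zscore = zscore,
      observed = y, predicted = pred, rating_trials = rating_trials
    ),
    class = "happiness_fit"
  )
}

hm_flagged_fit <- function(model, spec, n, flag) {
  structure(
    list(par = NULL,
         weights = stats::setNames(rep(NA_real_, length(spec$terms)),
                                   spec$terms),
         gamma = NA_real_, rp = NULL, w0 = NA_real_, logLik = NA_real_,
         bic = NA_real_, r2 = NA_real_, r2_ve = NA_real_, n_ratings = n,
         model = model, k = spec$k, flag = flag, zscore = NA,
         observed = NULL, predicted = NULL, rating_trials = integer()),
    class = "happiness_fit"
  )
}

#' @export
print.happiness_fit <- function(x, ...) {
  cat(sprintf("<happiness_fit: %s (%s)>\n", x$model, x$flag))
  if (identical(x$flag, "degenerate")) return(invisible(x))
  cat(sprintf("  w0 %.3f | gamma %.3f%s\n", x$w0, x$gamma,
              if (!is.null(x$rp)) sprintf(" | RP %.1f", x$rp) else ""))
  print(round(x$weights, 4))
  cat(sprintf("  r2 %.3f | BIC %.2f | n_ratings %d\n", x$r2, x$bic,
              x$n_ratings))
  invisible(x)
}

#' Two-stage happiness fit across both environments
#'
#' Mirrors the joint-then-separate protocol: a single parameter set is first
#' fitted to the pooled rating data of both environments (decayed histories
#' computed within each environment), and each environment is then refitted
#' separately with the joint fit seeding the forgetting-factor search.
#'
#' @param session_stable,session_volatile Session tibbles for the two
#'   environments of one subject.
#' @param terms_stable,terms_volatile Matching term histories.
#' @param model Model id.
#' @param zscore Standardise ratings within each environment (default
#'   `TRUE`).
#' @param ... Passed to [fit_happiness_model()].
#'
#' @return A list with elements `joint` (a `happiness_fit` on the pooled
#'   data), `stable` and `volatile`.
#' @export
fit_happiness_two_stage <- function(session_stable, session_volatile,
                                    terms_stable, terms_volatile, model,
                                    zscore = TRUE, ...) {
  spec <- hm_model(model)
  pooled <- hm_pool_sessions(list(session_stable, session_volatile),
                             list(terms_stable, terms_volatile), zscore)
  joint <- fit_happiness_model(pooled$session, pooled$terms, model,
                               zscore = FALSE, ...)
  list(
    joint = joint,
    stable = fit_happiness_model(session_stable, terms_stable, model,
                                 zscore = zscore, init = joint$par, ...),
    volatile = fit_happiness_model(session_volatile, terms_volatile, model,
                                   zscore = zscore, init = joint$par, ...)
  )
}

# stack sessions for a joint fit; a `.block` column keeps the decayed
# histories from crossing the environment boundary (hm_design restarts the
# recursion at each block)
hm_pool_sessions <- function(sessions, terms_list, zscore) {
  offs <- 0L
  ses_rows <- list()
  term_rows <- list()
  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    tms <- terms_list[[i]]
    if (zscore) {
      idx <- ses$is_rating_trial & !is.na(ses$rating)
      ses$rating[idx] <- as.numeric(scale(ses$rating[idx]))
    }
    ses$trial <- ses$trial + offs
    tms$trial <- tms$trial + offs
    tms$.block <- i
    offs <- offs + nrow(ses)
    ses_rows[[i]] <- ses
    term_rows[[i]] <- tms
  }
  session <- dplyr::bind_rows(ses_rows)
  terms <- dplyr::bind_rows(term_rows)
  list(session = session, terms = terms)
}

#' Refit a happiness model with the other environment's learning rate
#'
#' Rebuilds the term history using a learning rate estimated in the other
#' environment (the "wrong" rate), refits the happiness model, and so
#' probes whether the forgetting factor depends on the learning rate used
#' to construct subjective probabilities.
#'
#' @param session Session tibble.
#' @param alpha_other_env Learning rate from the other environment.
#' @param model Model id.
#' @param ... Passed to [fit_happiness_model()].
#'
#' @return A `happiness_fit`.
#' @export
swap_learning_rate_refit <- function(session, alpha_other_env, model,
                                     ...) {
  terms <- build_term_history(session, alpha_other_env)
  fit_happiness_model(session, terms, model, ...)
}

#' Simulate happiness ratings for a session
#'
#' Generates ratings at the session's rating trials from a happiness model
#' driven by the agent's own belief trace (the generating learning rate),
#' plus i.i.d. Gaussian noise. On the `"z"` scale the rating is the model
#' prediction plus noise; on the `"raw"` scale it is mapped to the 0-100
#' slider as `w0_raw + scale_factor * (prediction + noise)` and clipped.
#'
#' @param session Session tibble from [simulate_agent()].
#' @param params A [happiness_params()] (weights on the z scale).
#' @param alpha Generating learning rate used to build the term history.
#' @param noise_sd Rating noise SD in z units (default 0.6, at which
#'   the generative model accounts for roughly 60% of rating variance).
#' @param scale `"z"` or `"raw"`.
#' @param w0_raw Baseline on the 0-100 scale (raw scale only).
#' @param scale_factor Points per z unit for the raw mapping (default 15).
#' @param seed Optional integer seed.
#'
#' @return The session with its `rating` column filled at rating trials;
#'   the clipping rate (raw scale) is recorded in the `"clip_rate"`
#'   attribute.
#' @export
simulate_ratings <- function(session, params, alpha, noise_sd = 0.6,
                             scale = c("z", "raw"), w0_raw = 50,
                             scale_factor = 15, seed = NULL) {
  scale <- match.arg(scale)
  if (!is.null(seed)) withr::local_seed(seed)
  terms <- build_term_history(session, alpha)
  rating_trials <- which(session$is_rating_trial)
  zpred <- predict_happiness(params, terms, rating_trials)
  noise <- stats::rnorm(length(rating_trials), 0, noise_sd)
  z <- zpred + noise
  out <- session
  clip_rate <- 0
  if (scale == "z") {
    out$rating[rating_trials] <- z
  } else {
    raw <- w0_raw + scale_factor * z
    clip_rate <- mean(raw < 0 | raw > 100)
    out$rating[rating_trials] <- pmin(pmax(raw, 0), 100)
  }
  attr(out, "clip_rate") <- clip_rate
  out
}

#' Fit happiness models across a cohort
#'
#' For each subject x environment session: fits the additive choice model
#' (or reuses supplied fits) to obtain the learning rate, builds the term
#' history, and fits the requested happiness models.
#'
#' @param trials Long trial tibble with `subject`, `environment`, the
#'   schedule columns, `choice`, `outcome`, `obtained_points`, `rating`,
#'   `is_rating_trial`.
#' @param models Character vector of happiness-model ids.
#' @param choice_fits Optional tibble from [fit_choice_cohort()]
#'   (additive rows are used); fitted on the fly when `NULL`.
#' @param zscore,gamma_grid_step Passed to [fit_happiness_model()].
#' @param n_starts,seed Passed to the choice fitting.
#'
#' @return A tibble, one row per subject x environment x model, with the
#'   fitted baseline, weights (`w_1` for the first term, `w_2` for the
#'   second), `gamma`, `rp`, `r2`, `bic`, `n_ratings`, `flag` and the
#'   learning rate used.
#' @export
fit_happiness_cohort <- function(trials, models = "p_ppe",
                                 choice_fits = NULL, zscore = TRUE,
                                 gamma_grid_step = 0.01, n_starts = 10,
                                 seed = NULL) {
  if (is.null(choice_fits)) {
    choice_fits <- fit_choice_cohort(trials, models = "additive",
                                     n_starts = n_starts, seed = seed)
  }
  add_fits <- dplyr::filter(choice_fits, .data$model == "additive")
  sessions <- dplyr::group_split(
    dplyr::group_by(trials, .data$subject, .data$environment)
  )
  purrr::map_dfr(sessions, function(ses) {
    sub <- ses$subject[1]
    env <- ses$environment[1]
    row <- dplyr::filter(add_fits, .data$subject == sub,
                         .data$environment == env)
    if (nrow(row) != 1L) {
      stop("no additive choice fit for subject ", sub, " / ", env,
           call. = FALSE)
    }
    terms <- build_term_history(ses, row$alpha)
    purrr::map_dfr(models, function(m) {
      fit <- fit_happiness_model(ses, terms, m, zscore = zscore,
                                 gamma_grid_step = gamma_grid_step)
      w <- fit$weights
      tibble::tibble(
        subject = sub, environment = env, model = m, alpha_used = row$alpha,
        w0 = fit$w0,
        w_1 = unname(w[1]), w_2 = if (length(w) > 1) unname(w[2]) else
          NA_real_,
        term_1 = names(w)[1], term_2 = if (length(w) > 1) names(w)[2] else
          NA_character_,
        gamma = fit$gamma, rp = if (is.null(fit$rp)) NA_real_ else fit$rp,
        r2 = fit$r2, logLik = fit$logLik, bic = fit$bic,
        n_ratings = fit$n_ratings, flag = fit$flag
      )
    })
  })
}
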