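#' Choice-model parameter sets
#'
#' Bundles the free parameters of one of the four choice selectors. All
#' selectors share the same Rescorla-Wagner learner over the win probability
#' (except the magnitude-only selector, which has no learner):
#' the belief about car A is updated by a fraction `alpha` of the probability
#' prediction error each trial, and choices follow a logistic (softmax) rule
#' with inverse temperature `beta`.
#'
#' * `additive` - logistic in `phi * dP + (1 - phi) * dR`, with `dP` the
#'   belief difference and `dR` the offered-reward difference rescaled by the
#'   maximum reward; free parameters `(alpha, beta, phi)`.
#' * `multiplicative` - expected-utility style: `EU = clip(eta * (P - 0.5)
#'   + 0.5, 0, 1) * R` with rewards rescaled by the maximum reward so the
#'   shared `beta` bound is comparable across selectors; free parameters
#'   `(alpha, beta, eta)`.
#' * `probability_only` - additive with `phi` fixed at 1; `(alpha, beta)`.
#' * `magnitude_only` - additive with `phi` fixed at 0 and no learner;
#'   `(beta)`.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param beta Inverse temperature in `[0, 50]`.
#' @param phi Probability-magnitude weight in `[0, 1]` (additive family).
#' @param eta Probability-distortion / risk parameter in `[0, 10]`
#'   (multiplicative model).
#' @param model One of `"additive"`, `"multiplicative"`,
#'   `"probability_only"`, `"magnitude_only"`.
#'
#' @return A list of class `choice_params`.
#' @export
#' @examples
#' choice_params(alpha = 0.16, beta = 10, phi = 0.57)
choice_params <- function(alpha = NULL, beta = NULL, phi = NULL, eta = NULL,
                          model = c("additive", "multiplicative",
                                    "probability_only", "magnitude_only")) {
  model <- match.arg(model)
  need <- choice_model_free_params(model)
  vals <- list(alpha = alpha, beta = beta, phi = phi, eta = eta)
  for (p in need) {
    if (is.null(vals[[p]])) {
      stop(sprintf("model '%s' requires parameter `%s`", model, p),
           call. = FALSE)
    }
    b <- choice_param_bounds()[[p]]
    if (vals[[p]] < b[1] || vals[[p]] > b[2]) {
      stop(sprintf("`%s` = %g outside bounds [%g, %g]", p, vals[[p]],
                   b[1], b[2]), call. = FALSE)
    }
  }
  structure(c(vals[need], list(model = model)), class = "choice_params")
}

choice_model_free_params <- function(model) {
  switch(model,
    additive = c("alpha", "beta", "phi"),
    multiplicative = c("alpha", "beta", "eta"),
    probability_only = c("alpha", "beta"),
    magnitude_only = "beta",
    stop("unknown choice model: ", model, call. = FALSE)
  )
}

choice_param_bounds <- function() {
  list(alpha = c(0, 1), beta = c(0, 50), phi = c(0, 1), eta = c(0, 10))
}

#' Rescorla-Wagner belief update
#'
#' One delta-rule step on the estimated probability that car A wins. The
#' race is fully observed (exactly one car wins), so the belief about car B
#' is always the complement `1 - p_A` and a single latent probability
#' suffices for both cars.
#'
#' @param p_A Current estimate that car A wins, in `[0, 1]`.
#' @param outcome_A 1 if car A won the race, 0 otherwise.
#' @param alpha Learning rate in `[0, 1]`.
#'
#' @return A list with `p_next` (updated estimate) and `ppe` (the signed
#'   probability prediction error `outcome_A - p_A`).
#' @export
#' @examples
#' update_belief(0.5, 1, 0.5)  # ppe 0.5, p_next 0.75
update_belief <- function(p_A, outcome_A, alpha) {
  if (any(p_A < 0 | p_A > 1)) stop("`p_A` must lie in [0, 1].", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) {
    stop("`alpha` must lie in [0, 1].", call. = FALSE)
  }
  ppe <- outcome_A - p_A
  list(p_next = p_A + alpha * ppe, ppe = ppe)
}

#' Replay the belief trace over a session
#'
#' Runs the Rescorla-Wagner learner along an observed winner sequence.
#' Beliefs start at 0.5 and are never reset (reversals in the volatile task
#' are unsignalled). Because both cars' outcomes are observed every trial,
#' the trace depends only on the winner sequence and `alpha`, not on the
#' agent's choices.
#'
#' @param winner Character vector of per-trial winners (`"A"`/`"B"`).
#' @param alpha Learning rate in `[0, 1]`.
#' @param p0 Initial belief (default 0.5).
#'
#' @return A tibble with per-trial `p_A` (belief at choice time, before the
#'   trial's outcome) and `ppe_A` (prediction error for car A on that trial).
#' @export
replay_beliefs <- function(winner, alpha, p0 = 0.5) {
  n <- length(winner)
  outcome_A <- as.numeric(winner == "A")
  p <- numeric(n)
  ppe <- numeric(n)
  cur <- p0
  for (t in seq_len(n)) {
    p[t] <- cur
    ppe[t] <- outcome_A[t] - cur
    cur <- cur + alpha * ppe[t]
  }
  tibble::tibble(p_A = p, ppe_A = ppe)
}

#' Probability of choosing car A under a choice selector
#'
#' @param params A [choice_params()].
#' @param p_A Belief that car A wins (vectorised).
#' @param reward_A,reward_B Offered rewards in points (vectorised).
#' @param max_reward Reward normaliser (default 80, the maximum offered
#'   reward).
#'
#' @return Numeric vector of probabilities of choosing A, in `(0, 1)`.
#' @export
#' @examples
#' pars <- choice_params(alpha = 0.5, beta = 10, phi = 0.5)
#' choice_probability(pars, p_A = 0.8, reward_A = 10, reward_B = 30)
choice_probability <- function(params, p_A, reward_A, reward_B,
                               max_reward = 80) {
  stopifnot(inherits(params, "choice_params"))
  plogis_ <- function(x) 1 / (1 + exp(-x))
  switch(params$model,
    additive = {
      dP <- p_A - (1 - p_A)
      dR <- (reward_A - reward_B) / max_reward
      plogis_(params$beta * (params$phi * dP + (1 - params$phi) * dR))
    },
    probability_only = {
      dP <- p_A - (1 - p_A)
      plogis_(params$beta * dP)
    },
    magnitude_only = {
      dR <- (reward_A - reward_B) / max_reward
      plogis_(params$beta * dR)
    },
    multiplicative = {
      distort <- function(p) pmax(pmin(params$eta * (p - 0.5) + 0.5, 1), 0)
      eu_A <- distort(p_A) * reward_A / max_reward
      eu_B <- distort(1 - p_A) * reward_B / max_reward
      plogis_(params$beta * (eu_A - eu_B))
    }
  )
}

#' Simulate an agent on a schedule
#'
#' Plays a choice model through a generated schedule: beliefs are replayed
#' from the winner sequence (initialised at 0.5), each trial's choice is
#' sampled from [choice_probability()], and obtained points are the chosen
#' car's offered reward when it wins, 0 otherwise.
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param params A [choice_params()].
#' @param seed Optional integer seed for the choice sampling.
#'
#' @return The schedule tibble with added columns `choice` (`"A"`/`"B"`),
#'   `outcome` (1 win / 0 loss for the chosen car), `obtained_points`, and
#'   `rating` (all `NA`; filled by [simulate_ratings()]).
#' @export
simulate_agent <- function(schedule, params, seed = NULL) {
  stopifnot(inherits(params, "choice_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  alpha <- if (is.null(params$alpha)) 0 else params$alpha
  beliefs <- replay_beliefs(schedule$winner, alpha)
  p_choose_A <- choice_probability(params, beliefs$p_A,
                                   schedule$reward_A, schedule$reward_B)
  choice <- ifelse(stats::runif(nrow(schedule)) < p_choose_A, "A", "B")
  outcome <- as.integer(choice == schedule$winner)
  reward_chosen <- ifelse(choice == "A", schedule$reward_A,
                          schedule$reward_B)
  out <- schedule
  out$choice <- choice
  out$outcome <- outcome
  out$obtained_points <- as.integer(reward_chosen * outcome)
  out$rating <- NA_real_
  out
}

# belief trace without the tibble overhead of replay_beliefs(); used inside
# the likelihood loop
replay_pA <- function(outcome_A, alpha, p0 = 0.5) {
  n <- length(outcome_A)
  p <- numeric(n)
  cur <- p0
  for (t in seq_len(n)) {
    p[t] <- cur
    cur <- cur + alpha * (outcome_A[t] - cur)
  }
  p
}

# negative log likelihood closure over one session; theta is in the
# model's free-parameter order
make_choice_nll <- function(session, model, max_reward = 80) {
  outcome_A <- as.numeric(session$winner == "A")
  chose_A <- session$choice == "A"
  rA <- session$reward_A
  rB <- session$reward_B
  dR <- (rA - rB) / max_reward
  plogis_ <- function(x) 1 / (1 + exp(-x))
  function(theta) {
    pA_choice <- switch(model,
      additive = {
        p_A <- replay_pA(outcome_A, theta[1])
        plogis_(theta[2] * (theta[3] * (2 * p_A - 1) +
                              (1 - theta[3]) * dR))
      },
      probability_only = {
        p_A <- replay_pA(outcome_A, theta[1])
        plogis_(theta[2] * (2 * p_A - 1))
      },
      magnitude_only = plogis_(theta[1] * dR),
      multiplicative = {
        p_A <- replay_pA(outcome_A, theta[1])
        clip01 <- function(x) pmax(pmin(x, 1), 0)
        eu_A <- clip01(theta[3] * (p_A - 0.5) + 0.5) * rA / max_reward
        eu_B <- clip01(theta[3] * (0.5 - p_A) + 0.5) * rB / max_reward
        plogis_(theta[2] * (eu_A - eu_B))
      }
    )
    p_obs <- ifelse(chose_A, pA_choice, 1 - pA_choice)
    -sum(log(pmax(p_obs, 1e-12)))
  }
}

# convenience wrapper retained for direct likelihood checks
choice_nll <- function(theta, session, model, max_reward = 80) {
  make_choice_nll(session, model, max_reward)(theta)
}

#' Fit a choice model to one session by maximum likelihood
#'
#' Bounded maximum-likelihood estimation (L-BFGS-B) with `n_starts` uniform
#' random restarts inside the parameter bounds. Model evidence is summarised
#' by `BIC = k log(n) - 2 LL` and fit quality by McFadden's pseudo-r²
#' `1 - LL / (n log 0.5)` against the fair-coin chance likelihood.
#'
#' @param session A session tibble with `winner`, `reward_A`, `reward_B` and
#'   `choice` columns ([simulate_agent()] output or imported data).
#' @param model Choice model id; see [choice_params()].
#' @param n_starts Number of random restarts (default 10).
#' @param seed Optional integer seed making the restarts reproducible.
#' @param max_reward Reward normaliser for the additive family (default 80).
#'
#' @return An object of class `choice_fit`: a list with `par` (named
#'   estimates), `logLik`, `bic`, `pseudo_r2`, `n_trials`, `model`,
#'   `convergence` (0 if any restart converged) and `n_starts`.
#' @export
#' @examples
#' sched <- generate_schedule(task_config("stable"), seed = 1)
#' ses <- simulate_agent(sched, choice_params(0.16, 10, 0.57), seed = 2)
#' fit <- fit_choice_model(ses, "additive", seed = 3)
#' glance(fit)
fit_choice_model <- function(session, model = "additive", n_starts = 10,
                             seed = NULL, max_reward = 80) {
  if (length(unique(session$choice)) < 2L) {
    stop("session must contain at least two distinct choices", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  free <- choice_model_free_params(model)
  bounds <- choice_param_bounds()[free]
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  n <- nrow(session)
  nll <- make_choice_nll(session, model, max_reward)

  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(n_starts)) {
    start <- lower + stats::runif(length(free)) * (upper - lower)
    res <- tryCatch(
      stats::optim(start, nll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all optimiser restarts failed for model '", model, "'",
         call. = FALSE)
  }
  ll <- -best$value
  k <- length(free)
  par <- stats::setNames(best$par, free)
  structure(
    list(
      par = par, logLik = ll, bic = k * log(n) - 2 * ll,
      pseudo_r2 = 1 - ll / (n * log(0.5)), n_trials = n, model = model,
      k = k, convergence = if (any_conv) 0L else 1L, n_starts = n_starts
    ),
    class = "choice_fit"
  )
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("<choice_fit: %s>\n", x$model))
  print(round(x$par, 4))
  cat(sprintf("logLik %.2f | BIC %.2f | pseudo-r2 %.3f | n %d\n",
              x$logLik, x$bic, x$pseudo_r2, x$n_trials))
  invisible(x)
}

#' Fit choice models across a cohort
#'
#' Maps [fit_choice_model()] over every subject-by-environment session in a
#' long trial table and over one or more models, returning a tidy one row
#' per subject x environment x model.
#'
#' @param trials Long tibble of trials with at least `subject`,
#'   `environment`, `winner`, `reward_A`, `reward_B`, `choice`.
#' @param models Character vector of model ids.
#' @param n_starts,seed,max_reward Passed to [fit_choice_model()]; per-fit
#'   seeds are derived from `seed`.
#'
#' @return A tibble with `subject`, `environment`, `model`, the parameter
#'   columns (`alpha`, `beta`, `phi`, `eta`, `NA` where absent), `logLik`,
#'   `bic`, `pseudo_r2`, `n_trials`.
#' @export
fit_choice_cohort <- function(trials, models = "additive", n_starts = 10,
                              seed = NULL, max_reward = 80) {
  sessions <- dplyr::group_split(
    dplyr::group_by(trials, .data$subject, .data$environment)
  )
  grid <- tidyr::expand_grid(i = seq_along(sessions), model = models)
  purrr::pmap_dfr(grid, function(i, model) {
    ses <- sessions[[i]]
    fit_seed <- if (is.null(seed)) NULL else seed + 7919L * i +
      match(model, models)
    fit <- fit_choice_model(ses, model, n_starts = n_starts,
                            seed = fit_seed, max_reward = max_reward)
    tibble::tibble(
      subject = ses$subject[1], environment = ses$environment[1],
      model = model,
      alpha = par_or_na(fit$par, "alpha"),
      beta = par_or_na(fit$par, "beta"),
      phi = par_or_na(fit$par, "phi"),
      eta = par_or_na(fit$par, "eta"),
      logLik = fit$logLik, bic = fit$bic, pseudo_r2 = fit$pseudo_r2,
      n_trials = fit$n_trials
    )
  })
}

par_or_na <- function(par, nm) {
  if (nm %in% names(par)) unname(par[nm]) else NA_real_
}
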