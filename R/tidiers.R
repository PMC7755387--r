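#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted choice model
#'
#' @param x A `choice_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @exportS3Method generics::tidy
tidy.choice_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.choice_fit
#' @return `glance()` returns a one-row tibble with `model`, `logLik`,
#'   `bic`, `pseudo_r2`, `k`, `n_trials`, `convergence`.
#' @exportS3Method generics::glance
glance.choice_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik, bic = x$bic,
                 pseudo_r2 = x$pseudo_r2, k = x$k, n_trials = x$n_trials,
                 convergence = x$convergence)
}

#' Tidy a fitted happiness model
#'
#' @param x A `happiness_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (baseline, term weights,
#'   forgetting factor and, for the reference-point model, `rp`).
#' @exportS3Method generics::tidy
tidy.happiness_fit <- function(x, ...) {
  terms <- c("w0", names(x$weights), "gamma",
             if (!is.null(x$rp)) "rp")
  est <- c(x$w0, unname(x$weights), x$gamma,
           if (!is.null(x$rp)) x$rp)
  tibble::tibble(term = terms, estimate = est)
}

#' @rdname tidy.happiness_fit
#' @return `glance()` returns a one-row tibble with `model`, `logLik`,
#'   `bic`, `r2`, `r2_ve`, `k`, `n_ratings`, `flag`.
#' @exportS3Method generics::glance
glance.happiness_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik, bic = x$bic,
                 r2 = x$r2, r2_ve = x$r2_ve, k = x$k,
                 n_ratings = x$n_ratings, flag = x$flag)
}

#' Tidy a random-effects model-selection result
#'
#' @param x A `bms_result`.
#' @param ... Unused.
#' @return A tibble with one row per model: `model`, `dirichlet_alpha`,
#'   `expected_frequency`, `exceedance_probability`.
#' @exportS3Method generics::tidy
tidy.bms_result <- function(x, ...) {
  tibble::tibble(
    model = x$models,
    dirichlet_alpha = unname(x$dirichlet_alpha),
    expected_frequency = unname(x$expected_frequency),
    exceedance_probability = unname(x$exceedance_probability)
  )
}

#' @rdname tidy.bms_result
#' @return `glance()` returns a one-row tibble with `n_subjects`,
#'   `n_models`, `converged`, `n_iter`.
#' @exportS3Method generics::glance
glance.bms_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_models = length(x$models),
                 converged = x$converged, n_iter = x$n_iter)
}
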