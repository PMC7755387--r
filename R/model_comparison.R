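#' Fixed-effects model comparison by summed BIC
#'
#' Sums BIC over subjects for each model and reports the difference to a
#' reference model (the named preferred model, or the model with the lowest
#' summed BIC when unspecified). Lower BIC is better; a positive
#' `delta_bic` means the model loses to the reference.
#'
#' @param evidences Tibble with one row per subject x model and columns
#'   `subject`, `model`, `bic` (optionally `r2` or `pseudo_r2`, averaged
#'   into the report when present).
#' @param reference Optional reference model id.
#'
#' @return A tibble with `model`, `n_subjects`, `sum_bic`, `delta_bic`, and
#'   `mean_r2` when available, sorted by `sum_bic`.
#' @export
compare_fixed <- function(evidences, reference = NULL) {
  stopifnot(all(c("subject", "model", "bic") %in% names(evidences)))
  r2col <- intersect(c("r2", "pseudo_r2"), names(evidences))
  out <- dplyr::summarise(
    dplyr::group_by(evidences, .data$model),
    n_subjects = dplyr::n_distinct(.data$subject),
    sum_bic = sum(.data$bic),
    mean_r2 = if (length(r2col)) mean(.data[[r2col[1]]]) else NA_real_,
    .groups = "drop"
  )
  if (is.null(reference)) {
    reference <- out$model[which.min(out$sum_bic)]
  }
  if (!reference %in% out$model) {
    stop("reference model '", reference, "' not present", call. = FALSE)
  }
  ref_bic <- out$sum_bic[out$model == reference]
  out$delta_bic <- out$sum_bic - ref_bic
  dplyr::arrange(out[, c("model", "n_subjects", "sum_bic", "delta_bic",
                         "mean_r2")], .data$sum_bic)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects with an
#' unknown population distribution, following the variational Dirichlet
#' scheme: with per-subject log model evidences `l_nk` (here approximated
#' by `-BIC/2`) and a uniform Dirichlet prior (`alpha0 = 1`), it iterates
#' the subject-wise posterior model assignments
#' `u_nk proportional to exp(l_nk + psi(alpha_k) - psi(sum alpha))` and the
#' concentration update `alpha_k = alpha0 + sum_n u_nk` to convergence.
#' The exceedance probability - the posterior probability that a model is
#' the most frequent one in the population - is estimated by Monte-Carlo
#' sampling of the fitted Dirichlet.
#'
#' @param evidences Tibble with columns `subject`, `model` and either
#'   `log_evidence` or `bic` (converted as `-bic/2`); every subject must
#'   carry every model.
#' @param n_ep_samples Dirichlet samples for the exceedance probability
#'   (default 1e6, Monte-Carlo error below 0.001).
#' @param alpha0 Dirichlet prior concentration (default 1).
#' @param max_iter,tol Convergence controls for the variational loop.
#' @param seed Optional integer seed for the Monte-Carlo step.
#'
#' @return An object of class `bms_result`: a list with `models`,
#'   `dirichlet_alpha`, `expected_frequency`, `exceedance_probability`
#'   (all named by model), `assignment` (subjects x models posterior
#'   matrix), `n_subjects`, `converged`, `n_iter`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   subject = rep(1:8, each = 2), model = rep(c("a", "b"), 8),
#'   log_evidence = rep(c(0, -3), 8)
#' )
#' rfx_bms(ev, n_ep_samples = 1e4, seed = 1)
rfx_bms <- function(evidences, n_ep_samples = 1e6, alpha0 = 1,
                    max_iter = 500, tol = 1e-8, seed = NULL) {
  stopifnot(all(c("subject", "model") %in% names(evidences)))
  if (!"log_evidence" %in% names(evidences)) {
    if (!"bic" %in% names(evidences)) {
      stop("`evidences` needs a `log_evidence` or `bic` column",
           call. = FALSE)
    }
    evidences$log_evidence <- -evidences$bic / 2
  }
  wide <- tidyr::pivot_wider(
    evidences[, c("subject", "model", "log_evidence")],
    names_from = "model", values_from = "log_evidence"
  )
  models <- setdiff(names(wide), "subject")
  if (length(models) < 1L) stop("no models found", call. = FALSE)
  L <- as.matrix(wide[, models])
  if (anyNA(L)) stop("every subject must have evidence for every model",
                     call. = FALSE)
  n <- nrow(L)
  K <- ncol(L)
  # per-subject normalisation: only within-subject evidence differences
  # matter, and it guards exp() against overflow
  L <- L - apply(L, 1, max)

  alpha <- rep(alpha0, K)
  converged <- FALSE
  iter <- 0L
  u <- matrix(1 / K, n, K)
  while (iter < max_iter) {
    iter <- iter + 1L
    lw <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (sum(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }

  ef <- alpha / sum(alpha)
  ep <- if (K == 1L) 1 else {
    if (!is.null(seed)) withr::local_seed(seed)
    g <- matrix(stats::rgamma(n_ep_samples * K, shape = rep(alpha,
                                                            each = n_ep_samples)),
                nrow = n_ep_samples)
    winner <- max.col(g, ties.method = "random")
    tabulate(winner, nbins = K) / n_ep_samples
  }
  structure(
    list(
      models = models,
      dirichlet_alpha = stats::setNames(alpha, models),
      expected_frequency = stats::setNames(ef, models),
      exceedance_probability = stats::setNames(ep, models),
      assignment = u, n_subjects = n, converged = converged, n_iter = iter
    ),
    class = "bms_result"
  )
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("<bms_result: %d subjects, %d models%s>\n", x$n_subjects,
              length(x$models),
              if (x$converged) "" else ", NOT converged"))
  print(round(rbind(expected_frequency = x$expected_frequency,
                    exceedance_probability = x$exceedance_probability), 4))
  invisible(x)
}
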