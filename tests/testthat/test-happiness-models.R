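test_that("decayed sums match the direct brute-force evaluation", {
  expect_equal(decayed_sum(c(1, 0, 1), gamma = 0.5), 1.25)
  # memoryless and unweighted limits
  expect_equal(decayed_sum(c(3, 7, 2), gamma = 0), 2)
  expect_equal(decayed_sum(rep(1, 5), gamma = 1), 5)
  withr::local_seed(8)
  for (i in 1:25) {
    series <- rnorm(40)
    gamma <- runif(1)
    t <- sample(40, 1)
    expect_equal(decayed_sum(series, gamma, t),
                 decayed_sum_direct(series, gamma, t), tolerance = 1e-12)
  }
  expect_equal(decayed_trace(c(1, 0, 1), 0.5), c(1, 0.5, 1.25))
})

test_that("term history implements the prediction-error definitions", {
  session <- tibble::tibble(
    trial = 1:2,
    environment = "stable",
    best_car = c("A", "A"),
    winner = c("A", "B"),
    reward_A = c(40, 40), reward_B = c(10, 60),
    side_of_A = "left",
    is_rating_trial = FALSE,
    choice = c("A", "A"),
    outcome = c(1L, 0L),
    obtained_points = c(40L, 0L),
    rating = NA_real_
  )
  # alpha = 0.5: p_A = 0.5 then 0.75
  terms <- build_term_history(session, 0.5)
  expect_equal(terms$p_hat_chosen, c(0.5, 0.75))
  # win with P-hat 0.75 would give +0.25; here trial 2 is a loss: -0.75
  expect_equal(terms$ppe_hat, c(0.5, -0.75))
  # objective PPE after choosing the best car and winning: 1 - 0.8
  expect_equal(terms$ppe_obj, c(0.2, -0.8))
  # subjective RPE: obtained/80 minus P-hat * chosen reward/80
  expect_equal(terms$rpe_hat, c(0.5 - 0.5 * 0.5, 0 - 0.75 * 0.5))
  expect_equal(terms$rpe_obj, c(0.5 - 0.8 * 0.5, 0 - 0.8 * 0.5))
  expect_equal(terms$win_flag + terms$loss_flag, c(1, 1))
  expect_error(build_term_history(session, 1.3), "alpha")
})

test_that("equal weights reduce the probability+PPE model to a decayed win average", {
  # identity: w*(P-0.5) + w*(outcome-P) = w*(outcome - 0.5)
  withr::local_seed(9)
  for (i in 1:5) {
    ses <- make_session(sample(c("stable", "volatile"), 1), seed = 100 + i)
    terms <- build_term_history(ses, runif(1))
    w <- rnorm(1)
    gamma <- runif(1)
    pars <- happiness_params("p_ppe",
                             w0 = rnorm(1),
                             weights = c(p_hat_centered = w, ppe_hat = w),
                             gamma = gamma)
    rating_trials <- which(ses$is_rating_trial)
    pred <- predict_happiness(pars, terms, rating_trials)
    closed <- pars$w0 +
      w * decayed_trace(terms$win_flag - 0.5, gamma)[rating_trials]
    expect_equal(pred, closed, tolerance = 1e-12)
  }
})

test_that("all-zero weights predict the constant baseline", {
  ses <- make_session(seed = 3)
  terms <- build_term_history(ses, 0.3)
  pars <- happiness_params("p_ppe", w0 = 4.2,
                           weights = c(p_hat_centered = 0, ppe_hat = 0),
                           gamma = 0.6)
  expect_equal(predict_happiness(pars, terms, c(5L, 12L)), c(4.2, 4.2))
})

test_that("noise-free generation is recovered exactly", {
  ses <- make_rated_session(alpha = 0.4, w_p = 0.8, w_ppe = 1.1,
                            gamma = 0.59, noise_sd = 0, seed = 17)
  terms <- build_term_history(ses, 0.4)
  fit <- fit_happiness_model(ses, terms, "p_ppe", zscore = FALSE)
  expect_equal(unname(fit$weights["p_hat_centered"]), 0.8,
               tolerance = 1e-6)
  expect_equal(unname(fit$weights["ppe_hat"]), 1.1, tolerance = 1e-6)
  expect_equal(fit$gamma, 0.59, tolerance = 1e-6)
  expect_equal(fit$w0, 0, tolerance = 1e-8)
  expect_gt(fit$r2, 0.9999)
})

test_that("pure-noise and constant ratings are handled", {
  ses <- make_session(seed = 19)
  rating_trials <- which(ses$is_rating_trial)
  withr::local_seed(20)
  ses$rating[rating_trials] <- rnorm(length(rating_trials))
  terms <- build_term_history(ses, 0.3)
  fit <- fit_happiness_model(ses, terms, "p_ppe", zscore = FALSE)
  expect_lt(fit$r2, 0.4)
  ses$rating[rating_trials] <- 50
  fit2 <- fit_happiness_model(ses, terms, "p_ppe")
  expect_equal(fit2$flag, "degenerate")
  expect_true(is.na(fit2$gamma))
  ses$rating <- NA_real_
  ses$rating[rating_trials[1:3]] <- c(1, 2, 3)
  expect_error(fit_happiness_model(ses, terms, "p_ppe"), "5 ratings")
})

test_that("z-scored fits centre the baseline; raw fits respect its bounds", {
  ses <- make_rated_session(seed = 23, scale = "raw", w0_raw = 60)
  terms <- build_term_history(ses, 0.3)
  fit_z <- fit_happiness_model(ses, terms, "p_ppe", zscore = TRUE)
  expect_lt(abs(fit_z$w0), 0.3)
  fit_raw <- fit_happiness_model(ses, terms, "p_ppe", zscore = FALSE,
                                 w0_bounds = c(0, 100))
  expect_gte(fit_raw$w0, 0)
  expect_lte(fit_raw$w0, 100)
  expect_gt(fit_raw$w0, 20)  # near the generating baseline, not degenerate
})

test_that("the win-loss model recovers its sign convention", {
  ses <- make_session(seed = 29)
  terms <- build_term_history(ses, 0.3)
  pars <- happiness_params("winloss", w0 = 0.5,
                           weights = c(win_flag = 1.0, loss_flag = 0.8),
                           gamma = 0.55)
  rating_trials <- which(ses$is_rating_trial)
  ses$rating <- NA_real_
  ses$rating[rating_trials] <- predict_happiness(pars, terms, rating_trials)
  fit <- fit_happiness_model(ses, terms, "winloss", zscore = FALSE)
  expect_equal(unname(fit$weights["win_flag"]), 1.0, tolerance = 1e-5)
  expect_equal(unname(fit$weights["loss_flag"]), 0.8, tolerance = 1e-5)
  expect_equal(fit$gamma, 0.55, tolerance = 1e-5)
})

test_that("the reference-point model recovers RP inside its bounds", {
  ses <- make_session(seed = 31)
  terms <- build_term_history(ses, 0.3)
  pars <- happiness_params("r_rp", w0 = 0.2,
                           weights = c(r_points = 0.03), gamma = 0.5,
                           rp = 14)
  rating_trials <- which(ses$is_rating_trial)
  ses$rating <- NA_real_
  withr::local_seed(32)
  ses$rating[rating_trials] <-
    predict_happiness(pars, terms, rating_trials) +
    rnorm(length(rating_trials), 0, 0.02)
  fit <- fit_happiness_model(ses, terms, "r_rp", zscore = FALSE)
  expect_lt(abs(fit$rp - 14), 3)
  expect_gt(fit$rp, 0)
  expect_lt(abs(unname(fit$weights["r_points"]) - 0.03), 0.01)
})

test_that("model registry matches the stated parameter counts", {
  hm <- happiness_models()
  expect_equal(nrow(hm), 11L)
  expect_equal(hm$k[hm$model == "ppe_hat"], 3L)
  expect_equal(hm$k[hm$model == "p_ppe"], 4L)
  expect_equal(hm$k[hm$model == "winloss"], 4L)
  expect_equal(hm$k[hm$model == "r_rp"], 4L)
  expect_error(fit_happiness_model(make_session(), NULL, "nope"),
               "unknown happiness model")
})

test_that("swapping in the same learning rate is a no-op refit", {
  ses <- make_rated_session(alpha = 0.35, seed = 37)
  terms <- build_term_history(ses, 0.35)
  direct <- fit_happiness_model(ses, terms, "p_ppe", zscore = FALSE)
  swapped <- swap_learning_rate_refit(ses, 0.35, "p_ppe", zscore = FALSE)
  expect_equal(swapped$weights, direct$weights, tolerance = 1e-10)
  expect_equal(swapped$gamma, direct$gamma, tolerance = 1e-10)
  # a genuinely different rate changes the evidence but not gamma wildly
  other <- swap_learning_rate_refit(ses, 0.6, "p_ppe", zscore = FALSE)
  expect_false(isTRUE(all.equal(other$bic, direct$bic)))
})

test_that("swapped learning rates preserve the forgetting-factor ranking", {
  withr::local_seed(41)
  gammas <- runif(8, 0.3, 0.85)
  res <- t(vapply(seq_along(gammas), function(i) {
    ses <- make_rated_session(alpha = 0.16, gamma = gammas[i],
                              noise_sd = 0.4, seed = 500 + i)
    g1 <- fit_happiness_model(ses, build_term_history(ses, 0.16), "p_ppe",
                              zscore = FALSE)$gamma
    g2 <- swap_learning_rate_refit(ses, 0.47, "p_ppe",
                                   zscore = FALSE)$gamma
    c(g1, g2)
  }, numeric(2)))
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.5)
})

test_that("the two-stage protocol returns joint and per-environment fits", {
  ses_s <- make_rated_session("stable", alpha = 0.16, seed = 43)
  ses_v <- make_rated_session("volatile", alpha = 0.47, seed = 44)
  t_s <- build_term_history(ses_s, 0.16)
  t_v <- build_term_history(ses_v, 0.47)
  out <- fit_happiness_two_stage(ses_s, ses_v, t_s, t_v, "p_ppe")
  expect_s3_class(out$joint, "happiness_fit")
  expect_s3_class(out$stable, "happiness_fit")
  expect_s3_class(out$volatile, "happiness_fit")
  expect_equal(out$joint$n_ratings,
               out$stable$n_ratings + out$volatile$n_ratings)
  td <- tidy(out$stable)
  expect_true(all(c("w0", "gamma") %in% td$term))
})
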