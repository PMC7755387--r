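test_that("stay proportions respect degenerate strategies", {
  sched <- generate_schedule(task_config("volatile"), seed = 1)
  # perseverating agent: stays after every outcome
  ses <- sched
  ses$choice <- "A"
  ses$outcome <- as.integer(ses$choice == ses$winner)
  ses$obtained_points <- ses$reward_A * ses$outcome
  wsls <- win_stay_lose_shift(ses)
  expect_true(all(wsls$stay_after_win[!is.na(wsls$stay_after_win)] == 1))
  expect_true(all(wsls$stay_after_loss[!is.na(wsls$stay_after_loss)] == 1))
  # strict win-stay / lose-shift agent
  ses2 <- sched
  choice <- character(80)
  choice[1] <- "A"
  for (t in 2:80) {
    won <- choice[t - 1] == sched$winner[t - 1]
    choice[t] <- if (won) choice[t - 1] else
      ifelse(choice[t - 1] == "A", "B", "A")
  }
  ses2$choice <- choice
  ses2$outcome <- as.integer(choice == sched$winner)
  wsls2 <- win_stay_lose_shift(ses2)
  expect_true(all(wsls2$stay_after_win[wsls2$n_win > 0] == 1))
  expect_true(all(wsls2$stay_after_loss[wsls2$n_loss > 0] == 0))
  expect_error(win_stay_lose_shift(ses2[1, ]), "2 trials")
})

test_that("volatile agents show a larger win-stay differential than stable", {
  withr::local_seed(2)
  diff_for <- function(env, alpha, phi) {
    d <- vapply(1:15, function(i) {
      ses <- simulate_agent(generate_schedule(task_config(env)),
                            choice_params(alpha, 10, phi))
      w <- win_stay_lose_shift(ses)
      mean(w$stay_after_win - w$stay_after_loss, na.rm = TRUE)
    }, numeric(1))
    mean(d, na.rm = TRUE)
  }
  d_vol <- diff_for("volatile", 0.47, 0.44)
  d_sta <- diff_for("stable", 0.16, 0.57)
  expect_gt(d_vol, d_sta)
  expect_gt(d_vol, 0.1)
})

test_that("signed-rank test matches the reference implementation", {
  # textbook paired example: no zero differences, no tied magnitudes
  x <- c(125, 115, 130, 140, 115, 140, 125)
  y <- c(110, 122, 125, 120, 124, 123, 137)
  d <- x - y
  ours <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$v, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$n, sum(d != 0))
  # symmetric differences: p near 1
  sym <- wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3))
  expect_gt(sym$p, 0.9)
  # all-positive differences at n = 75 saturate near z = 7.5
  allpos <- wilcoxon_signed_rank(seq(0.5, 37.5, by = 0.5))
  expect_equal(allpos$z, 7.5, tolerance = 0.1)
  expect_lt(allpos$p, 1e-12)
  # tie-corrected normal approximation agrees with wilcox.test
  withr::local_seed(3)
  xx <- sample(1:5, 30, replace = TRUE)
  yy <- sample(1:5, 30, replace = TRUE)
  keep <- xx != yy
  ref2 <- suppressWarnings(
    stats::wilcox.test(xx[keep], yy[keep], paired = TRUE, exact = FALSE,
                       correct = TRUE)
  )
  ours2 <- wilcoxon_signed_rank(xx[keep], yy[keep])
  expect_equal(ours2$p, ref2$p.value, tolerance = 1e-10)
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "zero")
})

test_that("rank correlation handles ties and matches brute force", {
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:10, 10:1)$rho, -1)
  withr::local_seed(4)
  x <- sample(1:4, 25, replace = TRUE)
  y <- x + sample(0:2, 25, replace = TRUE)
  ours <- spearman(x, y)
  expect_equal(ours$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman(rep(1, 10), 1:10), "constant")
  expect_error(spearman(1:3, 3:1), "4 complete")
})

test_that("standardised-difference correlation recovers the built-in coupling", {
  withr::local_seed(5)
  n <- 100
  z <- rnorm(n)
  stable <- 55 + 14 * rnorm(n)
  volatile <- 49.5 + 14 * z
  symptom_hi <- -0.5 * z + sqrt(1 - 0.25) * rnorm(n)
  out <- standardized_difference_correlation(stable, volatile, symptom_hi)
  expect_lt(out$rho, -0.15)
  expect_lt(out$p, 0.05)
  # symptom independent of mood: near-zero correlation
  out0 <- standardized_difference_correlation(stable, volatile, rnorm(n))
  expect_lt(abs(out0$rho), 0.3)
  expect_error(
    standardized_difference_correlation(stable, stable, symptom_hi),
    "constant|identical"
  )
})

test_that("lagged PPE coefficients mirror the generating memory", {
  withr::local_seed(6)
  coef_mat <- function(gamma) {
    t(vapply(1:15, function(i) {
      ses <- make_rated_session(alpha = 0.3, w_p = 0, w_ppe = 1.2,
                                gamma = gamma, noise_sd = 0.3,
                                seed = 700 + i)
      terms <- build_term_history(ses, 0.3)
      lagged_ppe_regression(ses, terms)$estimate
    }, numeric(10)))
  }
  # memoryless generator: only the first lag carries weight
  m0 <- colMeans(coef_mat(0))
  expect_gt(m0[1], 0.5)
  expect_true(all(abs(m0[2:10]) < m0[1] / 2))
  # forgetful generator: coefficients decay roughly geometrically
  m6 <- colMeans(coef_mat(0.6))
  expect_gt(m6[1], m6[3])
  expect_gt(m6[3], m6[6])
  expect_gt(m6[3], 0)
})

test_that("win-loss residuals expose unmodelled probability influence", {
  withr::local_seed(7)
  rho_for <- function(w_p, w_ppe) {
    mean(vapply(1:12, function(i) {
      ses <- make_rated_session(alpha = 0.16, w_p = w_p, w_ppe = w_ppe,
                                noise_sd = 0.4, seed = 800 + i)
      terms <- build_term_history(ses, 0.16)
      fit <- fit_happiness_model(ses, terms, "winloss", zscore = FALSE)
      winloss_residual_probability_correlation(ses, fit, terms)$rho
    }, numeric(1)))
  }
  # generated with stronger PPE than probability weight: negative residual
  # correlation with the probability estimate
  expect_lt(rho_for(w_p = 0.3, w_ppe = 1.6), 0)
})

test_that("behavioural summary excludes tied expected values from accuracy", {
  sched <- generate_schedule(task_config("stable"), seed = 8)
  ses <- sched
  p_A <- ifelse(sched$best_car == "A", 0.8, 0.2)
  ev_A <- p_A * sched$reward_A
  ev_B <- (1 - p_A) * sched$reward_B
  ses$choice <- ifelse(ev_A >= ev_B, "A", "B")  # EV maximiser
  ses$outcome <- as.integer(ses$choice == ses$winner)
  ses$obtained_points <- 0L
  ses$rating <- NA_real_
  out <- behaviour_summary(ses)
  expect_equal(out$accuracy, 1)
  expect_equal(out$n_ratings, 0L)
  # metrics invariant to global car relabelling
  flip <- function(x) ifelse(x == "A", "B", "A")
  ses2 <- ses
  ses2$best_car <- flip(ses$best_car)
  ses2$winner <- flip(ses$winner)
  ses2$choice <- flip(ses$choice)
  ses2$reward_A <- ses$reward_B
  ses2$reward_B <- ses$reward_A
  out2 <- behaviour_summary(ses2)
  expect_equal(out2$accuracy, out$accuracy)
  expect_equal(out2$p_high_prob_choice, out$p_high_prob_choice)
  expect_equal(win_stay_lose_shift(ses2)$stay_after_win,
               win_stay_lose_shift(ses)$stay_after_win)
})

test_that("group environment table pairs subjects across environments", {
  withr::local_seed(9)
  per_subject <- tidyr::expand_grid(subject = 1:20,
                                    environment = c("stable", "volatile"))
  per_subject$alpha <- ifelse(per_subject$environment == "volatile",
                              rnorm(40, 0.47, 0.05), rnorm(40, 0.16, 0.05))
  tab <- group_environment_table(per_subject, "alpha")
  expect_equal(tab$metric, "alpha")
  expect_equal(tab$volatile_mean - tab$stable_mean, 0.31, tolerance = 0.1)
  expect_lt(tab$p, 0.001)
})
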