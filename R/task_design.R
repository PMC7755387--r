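#' Reward pairs offered in the car-race bandit
#'
#' The ten (left, right) point pairs from which each trial's offer is drawn
#' uniformly with replacement. Asymmetric pairs appear in both orders so that
#' each screen side carries the larger reward equally often.
#'
#' @format A list of length-2 integer vectors `c(left, right)`.
#' @export
reward_pairs_default <- list(
  c(10L, 10L), c(10L, 40L), c(10L, 60L), c(10L, 80L), c(20L, 40L),
  c(40L, 10L), c(40L, 20L), c(40L, 40L), c(60L, 10L), c(80L, 10L)
)

#' Task configuration for a car-race bandit session
#'
#' Describes one environment of the two-car race task: a one-armed bandit in
#' which exactly one car wins each race. The better car wins with probability
#' `p_best`, enforced exactly within every `sub_block_len`-trial sub-block
#' (`wins_per_sub_block` best-car wins out of `sub_block_len`). In the
#' volatile environment the identity of the better car reverses every
#' `block_len` trials; in the stable environment it is fixed throughout.
#'
#' @param environment `"stable"` or `"volatile"`.
#' @param n_trials Number of trials (default 80); must be a multiple of
#'   `sub_block_len`.
#' @param block_len Reversal period in trials for the volatile environment
#'   (default 20); must be a multiple of `sub_block_len`.
#' @param p_best Win probability of the better car (default 0.8). Must equal
#'   `wins_per_sub_block / sub_block_len`.
#' @param sub_block_len Length of the outcome pseudo-randomisation sub-block
#'   (default 10).
#' @param wins_per_sub_block Exact number of best-car wins per sub-block
#'   (default 8).
#' @param reward_pairs List of `(left, right)` point pairs offered; defaults
#'   to [reward_pairs_default].
#' @param rating_gap_choices Possible gaps (in trials) between happiness
#'   probes (default `c(3, 4)`).
#' @param side_swap_gap_range Range of gaps between screen-side swaps
#'   (default `c(6, 10)`).
#'
#' @return A list of class `task_config`.
#' @export
#' @examples
#' cfg <- task_config("volatile")
#' sched <- generate_schedule(cfg, seed = 1)
task_config <- function(environment = c("stable", "volatile"),
                        n_trials = 80L,
                        block_len = 20L,
                        p_best = 0.8,
                        sub_block_len = 10L,
                        wins_per_sub_block = 8L,
                        reward_pairs = reward_pairs_default,
                        rating_gap_choices = c(3L, 4L),
                        side_swap_gap_range = c(6L, 10L)) {
  environment <- match.arg(environment)
  n_trials <- as.integer(n_trials)
  block_len <- as.integer(block_len)
  sub_block_len <- as.integer(sub_block_len)
  wins_per_sub_block <- as.integer(wins_per_sub_block)
  if (n_trials %% sub_block_len != 0L) {
    stop("`n_trials` must be divisible by `sub_block_len`.", call. = FALSE)
  }
  if (block_len %% sub_block_len != 0L) {
    stop("`block_len` must be divisible by `sub_block_len`.", call. = FALSE)
  }
  if (abs(wins_per_sub_block / sub_block_len - p_best) > 1e-12) {
    stop("`wins_per_sub_block / sub_block_len` must equal `p_best`.",
         call. = FALSE)
  }
  if (!all(rating_gap_choices %in% c(3L, 4L))) {
    stop("`rating_gap_choices` must be a subset of {3, 4}.", call. = FALSE)
  }
  structure(
    list(
      environment = environment, n_trials = n_trials, block_len = block_len,
      p_best = p_best, sub_block_len = sub_block_len,
      wins_per_sub_block = wins_per_sub_block, reward_pairs = reward_pairs,
      rating_gap_choices = as.integer(rating_gap_choices),
      side_swap_gap_range = as.integer(side_swap_gap_range)
    ),
    class = "task_config"
  )
}

#' Place happiness-rating trials
#'
#' Rating probes occur after the outcome of a trial, separated by gaps drawn
#' uniformly from `gap_choices` (so with gaps of 3-4 trials an 80-trial
#' session carries roughly 20-26 probes). The first probe falls within the
#' first `max(gap_choices)` trials.
#'
#' @param n_trials Session length.
#' @param gap_choices Allowed gaps between consecutive probes, a subset of
#'   `c(3, 4)`.
#' @param seed Optional integer seed; the placement is a pure function of
#'   `(n_trials, gap_choices, seed)`.
#'
#' @return A logical vector of length `n_trials`, `TRUE` on rating trials.
#' @export
#' @examples
#' which(place_rating_trials(80, gap_choices = 3))
place_rating_trials <- function(n_trials, gap_choices = c(3L, 4L),
                                seed = NULL) {
  if (!all(gap_choices %in% c(3L, 4L))) {
    stop("`gap_choices` must be a subset of {3, 4}.", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  gap_choices <- as.integer(gap_choices)
  flags <- logical(n_trials)
  pos <- 0L
  repeat {
    gap <- if (length(gap_choices) == 1L) gap_choices else
      sample(gap_choices, 1L)
    pos <- pos + gap
    if (pos > n_trials) break
    flags[pos] <- TRUE
  }
  flags
}

# Screen-side assignment of car A: swapped every `gap_range` trials.
# Sides are cosmetic (beliefs attach to car identity) but recorded so that a
# schedule can be rendered exactly as presented.
place_side_swaps <- function(n_trials, gap_range = c(6L, 10L)) {
  side <- sample(c("left", "right"), 1L)
  sides <- character(n_trials)
  pos <- 1L
  while (pos <= n_trials) {
    gap <- sample(seq(gap_range[1], gap_range[2]), 1L)
    upto <- min(pos + gap - 1L, n_trials)
    sides[pos:upto] <- side
    side <- if (side == "left") "right" else "left"
    pos <- upto + 1L
  }
  sides
}

#' Generate a car-race bandit schedule
#'
#' Builds the full trial-level schedule for one environment: which car is the
#' better one on each trial, which car actually wins (pseudo-randomised so
#' the better car wins on exactly `wins_per_sub_block` of every
#' `sub_block_len` trials, in uniformly random order within the sub-block),
#' the offered reward pair (uniform with replacement from
#' `config$reward_pairs`), the screen side of car A, and the rating-probe
#' flags. In the volatile environment the better car flips every
#' `block_len` trials, with the initial better car chosen by coin flip; in
#' the stable environment one coin flip fixes it for the whole session.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed; the schedule is a pure function of
#'   `(config, seed)`.
#'
#' @return A tibble with one row per trial and columns `trial`,
#'   `environment`, `best_car`, `winner`, `reward_A`, `reward_B`,
#'   `side_of_A`, `is_rating_trial`. The seed is recorded in the
#'   `"seed"` attribute.
#' @export
#' @examples
#' sched <- generate_schedule(task_config("stable"), seed = 42)
#' mean(sched$winner == sched$best_car)  # exactly 0.8
generate_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- config$n_trials

  # better-car sequence
  first_best <- sample(c("A", "B"), 1L)
  other <- function(car) ifelse(car == "A", "B", "A")
  if (config$environment == "stable") {
    best_car <- rep(first_best, n)
  } else {
    block_id <- (seq_len(n) - 1L) %/% config$block_len
    best_car <- ifelse(block_id %% 2L == 0L, first_best, other(first_best))
  }

  # outcomes: exactly wins_per_sub_block best-car wins per sub-block,
  # uniformly permuted within the sub-block
  m <- config$sub_block_len
  best_wins <- unlist(lapply(seq_len(n / m), function(b) {
    sample(rep(c(TRUE, FALSE),
               c(config$wins_per_sub_block, m - config$wins_per_sub_block)))
  }))
  winner <- ifelse(best_wins, best_car, other(best_car))

  # offered rewards: pair gives (left, right); car A sits on side_of_A
  pair_idx <- sample(length(config$reward_pairs), n, replace = TRUE)
  left_pts <- vapply(config$reward_pairs[pair_idx], `[`, integer(1), 1L)
  right_pts <- vapply(config$reward_pairs[pair_idx], `[`, integer(1), 2L)
  side_of_A <- place_side_swaps(n, config$side_swap_gap_range)
  reward_A <- ifelse(side_of_A == "left", left_pts, right_pts)
  reward_B <- ifelse(side_of_A == "left", right_pts, left_pts)

  is_rating <- place_rating_trials(n, config$rating_gap_choices)

  out <- tibble::tibble(
    trial = seq_len(n),
    environment = config$environment,
    best_car = best_car,
    winner = winner,
    reward_A = as.integer(reward_A),
    reward_B = as.integer(reward_B),
    side_of_A = side_of_A,
    is_rating_trial = is_rating
  )
  attr(out, "seed") <- seed
  out
}
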