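#' Read and write trial tables
#'
#' The single interchange format of the package is a tidy long CSV with one
#' row per subject x environment x trial. Required columns: `subject`,
#' `environment` (`stable`/`volatile`), `trial` (1-based), `best_car`,
#' `winner`, `reward_A`, `reward_B`, `side_of_A`, `is_rating_trial`; choice
#' data add `choice`, `outcome`, `obtained_points`, `rating` (`NA` off
#' rating trials). Files start with `#`-prefixed metadata lines recording
#' the package version and, when supplied, the seed.
#'
#' @param trials A trial tibble (a single schedule is accepted; a `subject`
#'   column of 1s is added).
#' @param path File path.
#' @param seed Optional seed to record in the metadata header.
#'
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a validated tibble.
#' @export
write_trials <- function(trials, path, seed = NULL) {
  if (!"subject" %in% names(trials)) {
    trials <- dplyr::mutate(trials, subject = 1L, .before = 1)
  }
  header <- c(
    sprintf("# moodrl %s", as.character(utils::packageVersion("moodrl"))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else seed)
  )
  writeLines(header, path)
  readr::write_csv(trials, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_trials
#' @param require_choices Fail unless choice columns are present (set when
#'   reading input for model fitting).
#' @export
read_trials <- function(path, require_choices = FALSE) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  validate_trials(df, require_choices = require_choices)
}

validate_trials <- function(df, require_choices = FALSE) {
  required <- c("subject", "environment", "trial", "best_car", "winner",
                "reward_A", "reward_B", "is_rating_trial")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (require_choices) {
    missing_c <- setdiff(c("choice", "outcome", "obtained_points"),
                         names(df))
    if (length(missing_c)) {
      stop("trial table has no choice data (missing: ",
           paste(missing_c, collapse = ", "),
           "); supply a table with simulated or observed choices",
           call. = FALSE)
    }
  }
  check_values <- function(col, ok, what) {
    bad <- which(!ok)
    if (length(bad)) {
      stop(sprintf("column `%s`: %s (first bad row: %d)", col, what,
                   bad[1]), call. = FALSE)
    }
  }
  check_values("environment",
               df$environment %in% c("stable", "volatile"),
               "values must be 'stable' or 'volatile'")
  check_values("best_car", df$best_car %in% c("A", "B"),
               "values must be 'A' or 'B'")
  check_values("winner", df$winner %in% c("A", "B"),
               "values must be 'A' or 'B'")
  check_values("reward_A", is.finite(df$reward_A) & df$reward_A >= 0,
               "rewards must be non-negative numbers")
  check_values("reward_B", is.finite(df$reward_B) & df$reward_B >= 0,
               "rewards must be non-negative numbers")
  if ("choice" %in% names(df)) {
    check_values("choice", df$choice %in% c("A", "B"),
                 "values must be 'A' or 'B'")
    check_values("outcome", df$outcome %in% c(0, 1),
                 "values must be 0 or 1")
    check_values("outcome", df$outcome == (df$choice == df$winner),
                 "outcome flag inconsistent with winner and choice")
  }
  df$is_rating_trial <- as.logical(df$is_rating_trial)
  df
}

#' Read and write per-subject fit tables
#'
#' Fit tables (from [fit_choice_cohort()] or [fit_happiness_cohort()]) are
#' written as plain CSV with the same metadata header as trial tables.
#'
#' @param fits A fit tibble.
#' @param path File path.
#' @param seed Optional seed recorded in the header.
#' @export
write_fits <- function(fits, path, seed = NULL) {
  header <- c(
    sprintf("# moodrl %s", as.character(utils::packageVersion("moodrl"))),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else seed)
  )
  writeLines(header, path)
  readr::write_csv(fits, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
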