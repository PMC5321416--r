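# Canonical CSV schema, fixed order.
trial_columns <- c(
  "participant_id", "session", "trial_index", "choice",
  "stimulus_weight", "pain_rating", "cost"
)

sessions_allowed <- c("conditioning", "test")
choices_allowed <- c("doctor", "pharmacy", "control")

#' Validate a trial-level dataset
#'
#' Checks that a data frame of trials conforms to the medical-trust-game
#' paradigm: conditioning trials are doctor (64 or 256 mN) or pharmacy
#' (256 mN) choices, test trials always carry the 512 mN reference
#' stimulus, ratings and costs are nonnegative, and
#' `(participant, session, trial_index)` keys are unique.
#'
#' @param trials A data frame with columns `participant_id`, `session`,
#'   `trial_index`, `choice`, `stimulus_weight`, `pain_rating`, `cost`.
#' @return `trials` as a tibble, invisibly, if valid. Otherwise an error
#'   listing the offending rows.
#' @export
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) abort("`trials` must be a data frame.")
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`trials` is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "painbayes_schema_error")
  }
  trials <- as_tibble(trials)

  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) == 0) return(NULL)
    paste0(what, " (rows ", paste(head(rows, 10), collapse = ", "),
           if (length(rows) > 10) ", ..." else "", ")")
  }

  problems <- c(
    bad(!trials$session %in% sessions_allowed,
        "session not in {conditioning, test}"),
    bad(!trials$choice %in% choices_allowed,
        "choice not in {doctor, pharmacy, control}"),
    bad(!is.finite(trials$trial_index) | trials$trial_index < 1 |
          trials$trial_index != round(trials$trial_index),
        "trial_index must be a positive integer"),
    bad(!trials$stimulus_weight %in% c(64, 256, 512),
        "stimulus_weight not in {64, 256, 512} mN"),
    bad(!is.finite(trials$pain_rating) | trials$pain_rating < 0,
        "pain_rating must be finite and >= 0"),
    bad(!is.finite(trials$cost) | trials$cost < 0,
        "cost must be finite and >= 0"),
    bad(trials$session == "conditioning" & trials$choice == "control",
        "conditioning trials cannot have choice = control"),
    bad(trials$session == "conditioning" & trials$choice == "pharmacy" &
          trials$stimulus_weight != 256,
        "conditioning pharmacy trials must use 256 mN"),
    bad(trials$session == "conditioning" & trials$choice == "doctor" &
          !trials$stimulus_weight %in% c(64, 256),
        "conditioning doctor trials must use 64 or 256 mN"),
    bad(trials$session == "test" & trials$stimulus_weight != 512,
        "test trials must use the 512 mN reference stimulus"),
    bad(duplicated(trials[, c("participant_id", "session", "trial_index")]),
        "duplicate (participant_id, session, trial_index) key")
  )
  if (length(problems) > 0) {
    abort(paste0("Invalid trial data:\n", paste("-", problems, collapse = "\n")),
          class = "painbayes_validation_error")
  }
  invisible(trials)
}

#' Read and write trial-level datasets
#'
#' Trial data are stored as UTF-8 comma-separated text with a mandatory
#' header naming the seven schema columns
#' `participant_id,session,trial_index,choice,stimulus_weight,pain_rating,cost`.
#' Ratings are percent of the reference pain (reference = 100) and are not
#' clipped above 100 (magnitude estimation is unbounded above). Reading
#' validates the paradigm invariants and fails with row numbers on
#' violations; writing uses a fixed column order so output is byte-stable.
#'
#' @param path Path to a CSV file.
#' @param trials A valid trial tibble (see [validate_trials()]).
#' @return `read_trials()` returns a validated tibble of trials;
#'   `write_trials()` returns `trials` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' trials <- simulate_trust_game(population_config(n_participants = 2), seed = 1)$trials
#' write_trials(trials, f)
#' identical(nrow(read_trials(f)), nrow(trials))
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  trials <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session = readr::col_character(),
      trial_index = readr::col_integer(),
      choice = readr::col_character(),
      stimulus_weight = readr::col_double(),
      pain_rating = readr::col_double(),
      cost = readr::col_double()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(trials)
  if (nrow(probs) > 0) {
    abort(paste0("Unparseable values in ", path, " (first at row ",
                 probs$row[1], ", column ", probs$col[1], ")"),
          class = "painbayes_parse_error")
  }
  validate_trials(trials)
  trials[, trial_columns]
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials[, trial_columns], path, progress = FALSE)
  invisible(trials)
}

#' Filter trials by session, choice, or participant
#'
#' Row order is preserved; an empty result is legal. Passing `NULL` for a
#' predicate leaves that field unrestricted, so
#' `filter_trials(trials)` is the identity.
#'
#' @param trials A trial tibble.
#' @param session,choice,participant Optional values to keep (each may be a
#'   vector).
#' @return The filtered tibble.
#' @export
filter_trials <- function(trials, session = NULL, choice = NULL,
                          participant = NULL) {
  out <- as_tibble(trials)
  if (!is.null(session)) out <- out[out$session %in% session, ]
  if (!is.null(choice)) out <- out[out$choice %in% choice, ]
  if (!is.null(participant)) out <- out[out$participant_id %in% participant, ]
  out
}
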