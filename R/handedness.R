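#' Score participant handedness from observed activity-hand pairs
#'
#' Handedness is estimated from which hand a participant used for four
#' activities drawn from the Edinburgh Handedness Inventory: using scissors, a
#' spoon, and a knife with and without a fork. Each observed activity credits
#' one point to the hand that performed it; the hand with more points is the
#' participant's handedness. Ties are reported as `"undetermined"` with a
#' warning, and such participants should be excluded from handedness-stratified
#' tables rather than silently defaulted to one side.
#'
#' @param observations A data frame with columns `participant_id`, `activity`
#'   (one of `"scissors"`, `"spoon"`, `"knife_with_fork"`,
#'   `"knife_without_fork"`) and `hand_used` (`"left"`/`"right"`); at most one
#'   row per activity per participant and at least one row per scored
#'   participant.
#' @return A tibble with one row per participant: `participant_id`,
#'   `left_points`, `right_points`, `handedness`
#'   (`"left"`/`"right"`/`"undetermined"`).
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   participant_id = "P01",
#'   activity = c("scissors", "spoon", "knife_with_fork", "knife_without_fork"),
#'   hand_used = c("right", "right", "right", "left")
#' )
#' score_handedness(obs)  # right, 3 vs 1
score_handedness <- function(observations) {
  missing <- setdiff(c("participant_id", "activity", "hand_used"),
                     names(observations))
  if (length(missing) > 0) {
    abort(paste0("observations lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(observations) == 0) {
    abort("insufficient data: no handedness observations")
  }
  bad_act <- setdiff(unique(observations$activity), ACTIVITY_LEVELS)
  if (length(bad_act) > 0) {
    abort(paste0("unknown activity: ", paste(bad_act, collapse = ", ")))
  }
  if (!all(observations$hand_used %in% SIDE_LEVELS)) {
    abort("hand_used must be \"left\" or \"right\"")
  }
  dup <- observations |>
    dplyr::count(.data$participant_id, .data$activity) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate activity observation: participant ",
                 dup$participant_id[1], ", activity ", dup$activity[1]))
  }

  out <- observations |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      left_points = sum(.data$hand_used == "left"),
      right_points = sum(.data$hand_used == "right"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      handedness = dplyr::case_when(
        .data$right_points > .data$left_points ~ "right",
        .data$left_points > .data$right_points ~ "left",
        TRUE ~ "undetermined"
      )
    )
  ties <- out$participant_id[out$handedness == "undetermined"]
  if (length(ties) > 0) {
    warn(paste0("handedness undetermined (tied points) for participant(s): ",
                paste(ties, collapse = ", "),
                "; exclude them from handedness-stratified tables"))
  }
  out
}

#' Read handedness activity observations from a CSV file
#'
#' @param path CSV file with columns `participant_id`, `activity`,
#'   `hand_used`, one row per observed activity.
#' @return A tibble of observations suitable for [score_handedness()].
#' @export
read_handedness <- function(path) {
  if (!file.exists(path)) abort(paste0("handedness file not found: ", path))
  obs <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("participant_id", "activity", "hand_used"), names(obs))
  if (length(missing) > 0) {
    abort(paste0("handedness CSV lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  obs
}
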