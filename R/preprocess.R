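#' Per-participant catch-trial accuracy
#'
#' Proportion of correct catch (attention-check) trials per participant.
#'
#' @param trials trial table containing `trial_type == "catch"` rows with a
#'   logical `catch_correct` column.
#' @return Named numeric vector of accuracies in `[0, 1]`.
#' @export
catch_accuracy <- function(trials) {
  ctch <- trials[trials$trial_type == "catch", ]
  no_catch <- setdiff(unique(trials$participant_id), unique(ctch$participant_id))
  if (length(no_catch))
    stop("participants without catch trials: ", paste(no_catch, collapse = ", "))
  tapply(ctch$catch_correct, ctch$participant_id, mean)
}

#' Apply the catch-accuracy exclusion rule
#'
#' Participants whose catch accuracy falls strictly below the threshold are
#' removed from both the trial and the participant tables. A participant
#' exactly at the threshold is retained.
#'
#' @param cohort list with `trials` and `participants` data.frames.
#' @param threshold exclusion boundary, default 0.75.
#' @return A list with the retained `trials` and `participants` plus a
#'   `report` listing excluded ids, counts and the threshold.
#' @export
apply_exclusion <- function(cohort, threshold = 0.75) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  acc <- catch_accuracy(cohort$trials)
  excluded <- names(acc)[acc < threshold]
  keep_t <- !(cohort$trials$participant_id %in% excluded)
  keep_p <- !(cohort$participants$participant_id %in% excluded)
  list(trials = cohort$trials[keep_t, , drop = FALSE],
       participants = cohort$participants[keep_p, , drop = FALSE],
       report = list(threshold = threshold,
                     catch_accuracy = as.list(acc),
                     excluded_ids = excluded,
                     n_excluded = length(excluded),
                     n_retained = length(acc) - length(excluded)))
}

#' Build the analysis table of centred errors and radii
#'
#' Keeps emotional trials only (catch and neutral trials are dropped: no
#' model in the pipeline uses them), converts clicks to polar coordinates
#' and centres the response angle on the displayed emotion's correct
#' angle.
#'
#' @param trials trial table (post-exclusion) with click coordinates.
#' @param geometry a [gew_geometry()].
#' @return A data.frame with columns `participant_id`, `emotion`, `mask`,
#'   `intensity`, `error_deg` (in `(-180, 180]`), `radius_px`.
#' @export
prepare_model_table <- function(trials, geometry = gew_geometry()) {
  emo <- trials[trials$trial_type == "emotion", ]
  unknown <- setdiff(unique(emo$emotion), geometry$labels)
  if (length(unknown))
    stop("emotion labels not on the wheel: ", paste(unknown, collapse = ", "))
  pol <- click_to_polar(emo$click_x_px, emo$click_y_px, geometry)
  data.frame(participant_id = emo$participant_id,
             emotion = emo$emotion,
             mask = emo$mask,
             intensity = emo$intensity,
             error_deg = centered_error(pol$angle_deg,
                                        correct_angle(emo$emotion, geometry)),
             radius_px = pol$radius_px)
}
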