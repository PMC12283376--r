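#' Coordination rate of a transcript
#'
#' Fraction of rounds in which both players chose the same option (same
#' option index / label position), the success measure for coordination
#' games.
#'
#' @param transcript A completed transcript with at least one round.
#' @return A fraction in `[0, 1]`.
#' @export
coordination_rate <- function(transcript) {
  r <- transcript_rounds(transcript)
  if (nrow(r) == 0L) stop2("validation", "transcript has no completed rounds")
  m <- transcript$matrix
  i1 <- vapply(r$action_p1, function(a) option_index(m, 1L, a), integer(1))
  i2 <- vapply(r$action_p2, function(a) option_index(m, 2L, a), integer(1))
  mean(i1 == i2)
}

#' Joint cooperation rate of a transcript
#'
#' Fraction of rounds in which both players played the cooperate option.
#'
#' @inheritParams coordination_rate
#' @param cooperate_label Option label that counts as cooperation; by
#'   default taken from the game's `action_roles` metadata.
#' @return A fraction in `[0, 1]`.
#' @export
joint_cooperation_rate <- function(transcript, cooperate_label = NULL) {
  r <- transcript_rounds(transcript)
  if (nrow(r) == 0L) stop2("validation", "transcript has no completed rounds")
  m <- transcript$matrix
  if (is.null(cooperate_label)) {
    idx <- m$action_roles[["cooperate"]]
    if (is.null(idx)) {
      stop2("validation", "no cooperate option declared; pass `cooperate_label`")
    }
  } else {
    idx <- option_index(m, 1L, cooperate_label)
    if (!cooperate_label %in% c(player_options(m, 1L), player_options(m, 2L))) {
      stop2("validation", sprintf("'%s' is not a declared option", cooperate_label))
    }
  }
  i1 <- vapply(r$action_p1, function(a) option_index(m, 1L, a), integer(1))
  i2 <- vapply(r$action_p2, function(a) option_index(m, 2L, a), integer(1))
  mean(i1 == idx & i2 == idx)
}

#' Behaviour summary for one seat
#'
#' Per-player behaviour rates of a transcript: the defection rate (when
#' the game declares a defect option; `NA` otherwise — it is not guessed
#' for games without that structure), the preferred-option rate (fraction
#' of rounds the player chose its own preferred option), the coordination
#' and joint-cooperation rates, and the totals.
#'
#' @inheritParams coordination_rate
#' @param role Seat to summarize, 1 or 2.
#' @return A data frame with one row: `agent`, `role`, `defection_rate`,
#'   `preferred_option_rate`, `coordination_rate`,
#'   `joint_cooperation_rate`, `total_own`, `total_other`,
#'   `mean_per_round_own`.
#' @export
behaviour_rates <- function(transcript, role = 1L) {
  r <- transcript_rounds(transcript)
  if (nrow(r) == 0L) stop2("validation", "transcript has no completed rounds")
  m <- transcript$matrix
  own_actions <- if (role == 1L) r$action_p1 else r$action_p2
  own_idx <- vapply(own_actions, function(a) option_index(m, role, a), integer(1))

  def_idx <- m$action_roles[["defect"]]
  defection <- if (is.null(def_idx)) NA_real_ else mean(own_idx == def_idx)
  pref_idx <- option_index(m, role, preferred_option(m, role))
  coop <- tryCatch(joint_cooperation_rate(transcript), games2x2_error = function(e) NA_real_)
  totals <- transcript_totals(transcript)

  data.frame(
    agent = transcript$agent_names[role],
    role = role,
    defection_rate = defection,
    preferred_option_rate = mean(own_idx == pref_idx),
    coordination_rate = coordination_rate(transcript),
    joint_cooperation_rate = coop,
    total_own = totals[role],
    total_other = totals[3L - role],
    mean_per_round_own = totals[role] / nrow(r),
    stringsAsFactors = FALSE
  )
}

#' First round from which predictions stay correct
#'
#' The smallest round index `r` such that the prediction matches the actual
#' move in round `r` and every later round (e.g. "predicts the alternating
#' pattern correctly from round 5 onwards"). `NA` if the final prediction
#' is wrong.
#'
#' @param predictions A data frame with columns `predicted` and `actual`
#'   in round order (e.g. from [transcript_predictions()]).
#' @return An integer round index, or `NA_integer_`.
#' @export
first_sustained_correct_round <- function(predictions) {
  if (is.null(predictions) || nrow(predictions) == 0L) {
    stop2("validation", "`predictions` must have at least one row")
  }
  ok <- predictions$predicted == predictions$actual
  n <- length(ok)
  if (!ok[n]) return(NA_integer_)
  r <- n
  while (r > 1L && ok[r - 1L]) r <- r - 1L
  if (!is.null(predictions$round)) as.integer(predictions$round[r]) else r
}

#' Behaviour summaries for a batch of transcripts
#'
#' @param transcripts A list of transcripts.
#' @param keys Optional data frame of identifying columns (one row per
#'   transcript) prepended to the summary rows, e.g. game and variant ids.
#' @return A data frame with both seats' [behaviour_rates()] per
#'   transcript, suitable for CSV export.
#' @export
summarize_behaviour <- function(transcripts, keys = NULL) {
  rows <- lapply(seq_along(transcripts), function(i) {
    out <- rbind(behaviour_rates(transcripts[[i]], 1L),
                 behaviour_rates(transcripts[[i]], 2L))
    if (!is.null(keys)) out <- cbind(keys[rep(i, nrow(out)), , drop = FALSE], out)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
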