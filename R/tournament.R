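#' Build an all-pairs tournament schedule
#'
#' Every ordered pair of agents (including self-pairs, so each agent also
#' plays itself, and each unordered pair appears in both seatings) plays
#' every game once: `k` agents and `m` games give `k^2 * m` plays. Per-play
#' seeds are derived deterministically from `base_seed`.
#'
#' @param agents Character vector of agent ids (>= 1).
#' @param games Character vector of game ids (>= 1).
#' @param base_seed Integer seed from which all play seeds derive.
#' @return A data frame of class `schedule` with columns `play_id`,
#'   `game_id`, `agent1`, `agent2`, `seed`.
#' @export
build_schedule <- function(agents, games, base_seed = 1L) {
  if (length(agents) < 1L || length(games) < 1L) {
    stop2("validation", "need at least one agent and one game")
  }
  grid <- expand.grid(agent2 = agents, agent1 = agents, game_id = games,
                      stringsAsFactors = FALSE)[, c("game_id", "agent1", "agent2")]
  out <- data.frame(
    play_id = seq_len(nrow(grid)),
    grid,
    seed = as.integer((as.integer(base_seed) + seq_len(nrow(grid)) - 1L) %% .Machine$integer.max),
    stringsAsFactors = FALSE
  )
  class(out) <- c("schedule", "data.frame")
  out
}

#' Normalized score of one seat
#'
#' The player's achieved total divided by the total achievable under ideal
#' conditions (every round ending in that player's best cell); lies in
#' `[0, 1]` for non-negative pay-offs.
#'
#' @param transcript A completed transcript.
#' @param role Seat, 1 or 2.
#' @return A fraction.
#' @export
normalized_score <- function(transcript, role) {
  n <- length(transcript$rounds)
  if (n == 0L) stop2("validation", "transcript has no completed rounds")
  ideal <- max_ideal_score(transcript$matrix, role, n)
  if (ideal <= 0) stop2("undefined_metric", "ideal score is not positive; normalized score undefined")
  transcript_totals(transcript)[role] / ideal
}

#' Run a tournament
#'
#' Plays every schedule row through the match engine and aggregates mean
#' normalized scores per agent and family, pooling both seatings and
#' self-play. Plays aborted by unparseable text answers are tallied and
#' excluded from the means.
#'
#' @param schedule A [build_schedule()] data frame.
#' @param agents Named list of [agent_policy()] objects covering every
#'   agent id in the schedule.
#' @param games Named list of [payoff_matrix()] objects covering every game
#'   id; a `"family"` attribute on a game feeds the per-family aggregation
#'   (games without one are grouped under `"unknown"`).
#' @param config A [match_config()]; its seed field is superseded by the
#'   schedule's per-play seeds.
#' @param variant A shared [make_variant()] for both seats.
#' @param keep_transcripts Keep the full transcript archive in the result?
#'   Default `TRUE`.
#' @return An object of class `tournament_report`: list with `plays`
#'   (per-play data frame incl. normalized scores and status),
#'   `family_counts`, `agent_family` (mean normalized score per agent and
#'   family), `overall` (per agent), `n_aborted` and (optionally)
#'   `transcripts`.
#' @export
run_tournament <- function(schedule, agents, games, config = match_config(),
                           variant = make_variant(), keep_transcripts = TRUE) {
  missing_a <- setdiff(unique(c(schedule$agent1, schedule$agent2)), names(agents))
  if (length(missing_a)) {
    stop2("validation", sprintf("unresolvable agent id(s): %s", paste(missing_a, collapse = ", ")))
  }
  missing_g <- setdiff(unique(schedule$game_id), names(games))
  if (length(missing_g)) {
    stop2("validation", sprintf("unresolvable game id(s): %s", paste(missing_g, collapse = ", ")))
  }
  transcripts <- vector("list", nrow(schedule))
  rows <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    g <- games[[row$game_id]]
    cfg <- match_config(config$n_rounds, config$delta, row$seed)
    tr <- play_match(g, agents[[row$agent1]], agents[[row$agent2]], cfg,
                     variant1 = variant, on_abort = "return")
    transcripts[[i]] <- tr
    ok <- tr$status == "complete"
    rows[[i]] <- data.frame(
      play_id = row$play_id, game_id = row$game_id,
      family = attr(g, "family") %||% "unknown",
      agent1 = row$agent1, agent2 = row$agent2, seed = row$seed,
      status = tr$status,
      score_p1 = if (ok) normalized_score(tr, 1L) else NA_real_,
      score_p2 = if (ok) normalized_score(tr, 2L) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  plays <- do.call(rbind, rows)
  report <- aggregate_tournament(plays)
  if (keep_transcripts) report$transcripts <- transcripts
  report
}

#' Aggregate per-play results into a tournament report
#'
#' Pure aggregation: invariant to the order of `plays` rows, and replaying
#' an archive through it reproduces the identical report.
#'
#' @param plays A per-play data frame as produced by [run_tournament()]
#'   (`family`, `agent1`, `agent2`, `status`, `score_p1`, `score_p2`).
#' @return A `tournament_report` (without the transcript archive).
#' @export
aggregate_tournament <- function(plays) {
  done <- plays[plays$status == "complete", , drop = FALSE]
  # one observation per seat: each play yields a score for both agents
  long <- rbind(
    data.frame(agent = done$agent1, family = done$family, score = done$score_p1,
               stringsAsFactors = FALSE),
    data.frame(agent = done$agent2, family = done$family, score = done$score_p2,
               stringsAsFactors = FALSE)
  )
  counts <- stats::aggregate(list(n_plays = plays$play_id), by = list(family = plays$family), FUN = length)
  absent <- setdiff(game_families(), counts$family)
  if (length(absent)) {
    counts <- rbind(counts, data.frame(family = absent, n_plays = 0L))
  }
  counts <- counts[order(counts$family), , drop = FALSE]
  agent_family <- stats::aggregate(list(mean_score = long$score),
                                   by = list(agent = long$agent, family = long$family),
                                   FUN = mean)
  agent_family <- agent_family[order(agent_family$agent, agent_family$family), , drop = FALSE]
  overall <- stats::aggregate(list(mean_score = long$score),
                              by = list(agent = long$agent), FUN = mean)
  overall <- overall[order(overall$agent), , drop = FALSE]
  rownames(counts) <- rownames(agent_family) <- rownames(overall) <- NULL
  structure(
    list(plays = plays, family_counts = counts, agent_family = agent_family,
         overall = overall, n_aborted = sum(plays$status != "complete")),
    class = "tournament_report"
  )
}

#' @export
print.tournament_report <- function(x, ...) {
  cat(sprintf("tournament: %d plays (%d aborted)\n", nrow(x$plays), x$n_aborted))
  cat("\nplays per family:\n")
  print(x$family_counts, row.names = FALSE)
  cat("\nmean normalized score per agent and family:\n")
  print(score_table(x), digits = 3)
  invisible(x)
}

#' Family-by-agent score table
#'
#' Reshapes a tournament report into the conventional benchmark table:
#' one row per family (plus `overall`), one column per agent, entries the
#' mean normalized score.
#'
#' @param report A `tournament_report`.
#' @return A data frame (families x agents).
#' @export
score_table <- function(report) {
  af <- report$agent_family
  wide <- stats::reshape(af, idvar = "family", timevar = "agent", direction = "wide")
  names(wide) <- sub("^mean_score\\.", "", names(wide))
  rownames(wide) <- NULL
  ov <- data.frame(family = "overall", stringsAsFactors = FALSE)
  for (a in report$overall$agent) ov[[a]] <- report$overall$mean_score[report$overall$agent == a]
  rbind(wide, ov[names(wide)])
}
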