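#' Match configuration
#'
#' @param n_rounds Number of repetitions of the stage game (default 10).
#' @param delta Discount factor in `[0, 1]` applied as `delta^t` to the
#'   stage-`t` pay-off (default 1: plain totals).
#' @param seed Integer seed recorded with the match (all randomization in a
#'   run flows from recorded seeds; scripted play is deterministic anyway).
#' @return An object of class `match_config`.
#' @export
match_config <- function(n_rounds = 10L, delta = 1, seed = 1L) {
  if (!is.numeric(n_rounds) || length(n_rounds) != 1L || n_rounds < 1 ||
      n_rounds != round(n_rounds)) {
    stop2("validation", "`n_rounds` must be a whole number >= 1")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1) {
    stop2("validation", "`delta` must lie in [0, 1]")
  }
  structure(list(n_rounds = as.integer(n_rounds), delta = delta,
                 seed = as.integer(seed)),
            class = "match_config")
}

new_transcript <- function(matrix, agent_names, variant_p1, variant_p2, seed) {
  structure(
    list(matrix = matrix, agent_names = agent_names,
         variant_p1 = variant_p1, variant_p2 = variant_p2,
         seed = as.integer(seed), status = "complete", rounds = list()),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript: %s vs %s, %d round(s), status %s\n",
              x$agent_names[1], x$agent_names[2], length(x$rounds), x$status))
  if (length(x$rounds)) print(transcript_rounds(x))
  invisible(x)
}

#' Round-by-round view of a transcript
#'
#' @param transcript A transcript from [play_match()].
#' @return A data frame with columns `round`, `action_p1`, `action_p2`,
#'   `payoff_p1`, `payoff_p2`.
#' @export
transcript_rounds <- function(transcript) {
  if (length(transcript$rounds) == 0L) {
    return(data.frame(round = integer(0), action_p1 = character(0),
                      action_p2 = character(0), payoff_p1 = numeric(0),
                      payoff_p2 = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(transcript$rounds, function(r) {
    data.frame(round = r$round, action_p1 = r$action_p1, action_p2 = r$action_p2,
               payoff_p1 = r$payoff_p1, payoff_p2 = r$payoff_p2,
               stringsAsFactors = FALSE)
  }))
}

#' Total pay-offs of a transcript
#'
#' @inheritParams transcript_rounds
#' @param delta Optional discount factor; default 1 gives the plain totals.
#' @return Numeric vector `c(p1, p2)`.
#' @export
transcript_totals <- function(transcript, delta = 1) {
  rounds <- transcript_rounds(transcript)
  if (nrow(rounds) == 0L) return(c(0, 0))
  c(discounted_utility(rounds$payoff_p1, delta),
    discounted_utility(rounds$payoff_p2, delta))
}

#' Discounted repeated-game utility
#'
#' For per-stage pay-offs \eqn{\pi_0, \ldots, \pi_{n-1}} and discount
#' factor \eqn{\delta}, returns
#' \eqn{U = \sum_{t=0}^{n-1} \delta^t \pi_t}. With \eqn{\delta = 1} this is
#' the plain total; with \eqn{\delta = 0} only the first round counts.
#'
#' @param payoffs Non-empty numeric vector of per-round pay-offs, first
#'   round first.
#' @param delta Discount factor in `[0, 1]`.
#' @return A single number.
#' @export
discounted_utility <- function(payoffs, delta = 1) {
  if (!is.numeric(payoffs) || length(payoffs) == 0L) {
    stop2("validation", "`payoffs` must be a non-empty numeric vector")
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1) {
    stop2("validation", "`delta` must lie in [0, 1]")
  }
  sum(delta^(seq_along(payoffs) - 1L) * payoffs)
}

#' Play one finitely repeated match
#'
#' Runs `config$n_rounds` rounds of the simultaneous-move stage game. Each
#' round, both policies decide against the same frozen pre-round transcript
#' (neither can see the other's current-round action), the pay-off pair is
#' read from the matrix, and the round is appended to the history both
#' agents see next round.
#'
#' Actions are recorded under the matrix's own option labels regardless of
#' the prompt variant's tokens, so transcripts are comparable across
#' framing variants.
#'
#' @param matrix A [payoff_matrix()].
#' @param agent1,agent2 [agent_policy()] objects (seats 1 and 2).
#' @param config A [match_config()].
#' @param variant1,variant2 Prompt variants shown to each seat
#'   (default: one shared neutral variant).
#' @param on_abort What to do when a text agent's answer is unparseable:
#'   `"error"` (default) signals a `games2x2_aborted_match_error` carrying
#'   the partial transcript in its `transcript` field; `"return"` returns
#'   the partial transcript with `status = "aborted"` plus `abort_round`
#'   and `abort_reason` fields.
#' @return A `transcript` object.
#' @examples
#' pd <- canonical_game("prisoners_dilemma")
#' tr <- play_match(pd, scripted_agent("grim_trigger"),
#'                  scripted_agent("false_defector"))
#' transcript_totals(tr) # c(90, 10)
#' @export
play_match <- function(matrix, agent1, agent2, config = match_config(),
                       variant1 = make_variant(), variant2 = variant1,
                       on_abort = c("error", "return")) {
  on_abort <- match.arg(on_abort)
  agents <- list(agent1, agent2)
  variants <- list(variant1, variant2)
  for (a in agents) {
    if (!inherits(a, "agent_policy")) stop2("validation", "agents must be agent_policy objects")
    if (!is.null(a$reset)) a$reset()
  }
  tr <- new_transcript(matrix, c(agent1$name, agent2$name), variant1, variant2,
                       config$seed)
  for (t in seq_len(config$n_rounds)) {
    frozen <- tr  # both agents decide from the same pre-round history
    decisions <- vector("list", 2L)
    for (r in 1:2) {
      res <- tryCatch(
        agents[[r]]$decide(matrix, r, frozen, variants[[r]]),
        games2x2_unparseable_error = function(e) e
      )
      if (inherits(res, "games2x2_unparseable_error")) {
        tr$status <- "aborted"
        tr$abort_round <- t
        tr$abort_reason <- conditionMessage(res)
        if (on_abort == "return") return(tr)
        stop2("aborted_match",
              sprintf("match aborted in round %d (%s): %s",
                      t, agents[[r]]$name, conditionMessage(res)),
              transcript = tr)
      }
      decisions[[r]] <- normalize_decision(res)
    }
    acts <- vapply(1:2, function(r) {
      a <- decisions[[r]]$action
      i <- tryCatch(option_index(matrix, r, a), games2x2_protocol_error = function(e) {
        stop2("protocol", sprintf("agent '%s' returned undeclared label '%s' in round %d",
                                  agents[[r]]$name, a, t))
      })
      player_options(matrix, r)[i]
    }, character(1))
    pay <- payoff_at(matrix, acts[1], acts[2])
    rec <- list(round = t, action_p1 = acts[1], action_p2 = acts[2],
                payoff_p1 = pay[1], payoff_p2 = pay[2])
    for (r in 1:2) {
      pred <- decisions[[r]]$prediction
      if (!is.null(pred)) {
        pred$actual <- acts[3L - r]
        rec[[paste0("prediction_p", r)]] <- pred
      }
      if (!is.null(decisions[[r]]$distribution)) {
        rec[[paste0("distribution_p", r)]] <- decisions[[r]]$distribution
      }
    }
    tr$rounds[[t]] <- rec
  }
  tr
}

# a policy may return a bare label or a list(action, prediction, distribution)
normalize_decision <- function(res) {
  if (is.character(res) && length(res) == 1L) return(list(action = res))
  if (is.list(res) && !is.null(res$action)) return(res)
  stop2("protocol", "a policy must return an option label or a list with an `action` field")
}

#' Predictions recorded in a transcript
#'
#' @inheritParams transcript_rounds
#' @param role Seat whose predictions to extract (1 or 2).
#' @return A data frame with columns `round`, `predicted`, `actual`
#'   (zero rows if the seat recorded no predictions).
#' @export
transcript_predictions <- function(transcript, role) {
  key <- paste0("prediction_p", role)
  rows <- Filter(Negate(is.null), lapply(transcript$rounds, function(r) {
    p <- r[[key]]
    if (is.null(p)) return(NULL)
    data.frame(round = r$round, predicted = p$predicted, actual = p$actual,
               stringsAsFactors = FALSE)
  }))
  if (length(rows) == 0L) {
    return(data.frame(round = integer(0), predicted = character(0),
                      actual = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
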