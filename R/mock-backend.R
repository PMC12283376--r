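#' Deterministic mock text backend
#'
#' An offline [text_backend()] that behaves like the behavioural personas
#' observed in text-completion agents, implemented by actually parsing the
#' rendered prompt text (rules, history and query) and answering with a
#' one-hot token distribution. Running it end to end validates the whole
#' prompt-render/answer-parse loop without a live endpoint.
#'
#' Personas:
#' * `grim` — answers the cooperate token until the history shows a single
#'   opponent defection, then the defect token forever (the unforgiving
#'   signature; requires `label_map`).
#' * `cooperative` — always the cooperate token (requires `label_map`).
#' * `stubborn` — reads the rules clauses and always answers its own
#'   preferred option (the token of its maximum pay-off).
#' * `alternation_predictor` — for prediction queries, extrapolates the
#'   queried player's move pattern from the history (alternation if the
#'   last two moves differ, otherwise repetition); for choose queries it
#'   best-responds to the announced or extrapolated prediction.
#' * `scripted_replay` — plays `moves[t]` at round `t` (recycled),
#'   regardless of history.
#'
#' A prompt whose history section cannot be located raises a
#' `games2x2_contract_error`: it signals a prompting regression, not a
#' model answer.
#'
#' @param persona One of `"grim"`, `"cooperative"`, `"stubborn"`,
#'   `"alternation_predictor"`, `"scripted_replay"`.
#' @param label_map Named character vector mapping action roles to prompt
#'   tokens, e.g. `c(cooperate = "F", defect = "J")`. Required by the
#'   cooperate/defect personas; tokens must match the variant in use.
#' @param moves Character vector of tokens for `scripted_replay`.
#' @param description Backend identifier.
#' @return A [text_backend()].
#' @examples
#' pd <- canonical_game("prisoners_dilemma")
#' b <- mock_backend("grim", label_map = c(cooperate = "F", defect = "J"))
#' a <- text_agent(b, "mock_grim")
#' transcript_totals(play_match(pd, a, scripted_agent("false_defector")))
#' @export
mock_backend <- function(persona = c("grim", "cooperative", "stubborn",
                                     "alternation_predictor", "scripted_replay"),
                         label_map = NULL, moves = NULL,
                         description = paste0("mock_", persona[1])) {
  persona <- match.arg(persona)
  if (persona %in% c("grim", "cooperative")) {
    if (is.null(label_map) || !all(c("cooperate", "defect") %in% names(label_map))) {
      stop2("validation", sprintf(
        "persona '%s' needs label_map with 'cooperate' and 'defect' tokens", persona))
    }
  }
  if (persona == "scripted_replay" && (is.null(moves) || length(moves) == 0L)) {
    stop2("validation", "persona 'scripted_replay' needs a non-empty `moves` vector")
  }
  complete <- function(text) {
    p <- parse_prompt_text(text)
    token <- switch(persona,
      cooperative = unname(label_map[["cooperate"]]),
      grim = {
        betrayed <- nrow(p$history) > 0 &&
          any(p$history$other == label_map[["defect"]])
        unname(label_map[[if (betrayed) "defect" else "cooperate"]])
      },
      stubborn = {
        if (nrow(p$rules) == 0L) stop2("contract", "no parsable rules section in prompt")
        p$rules$own[which.max(p$rules$own_pay)]
      },
      alternation_predictor = mock_alternation_answer(p),
      scripted_replay = moves[(p$round - 1L) %% length(moves) + 1L]
    )
    stats::setNames(1, token)
  }
  text_backend(complete, temperature = 0, description = description)
}

mock_alternation_answer <- function(p) {
  extrapolate <- function(series) {
    n <- length(series)
    if (n == 0L) return(NULL)
    if (n >= 2L && series[n] != series[n - 1L]) {
      # alternating pattern: predict the move that is not the last one
      setdiff(unique(series[(n - 1L):n]), series[n])
    } else {
      series[n]
    }
  }
  if (p$query == "choose") {
    target <- p$prediction %||% extrapolate(p$history$other)
    if (is.null(target)) {
      # round 1, nothing to condition on: take the own-preferred option
      return(p$rules$own[which.max(p$rules$own_pay)])
    }
    rows <- p$rules[p$rules$other == target, , drop = FALSE]
    if (nrow(rows) == 0L) stop2("contract", "rules lack clauses for the predicted option")
    rows$own[which.max(rows$own_pay)]
  } else if (p$query == "predict") {
    ans <- extrapolate(p$history$other)
    if (is.null(ans)) p$options[1] else ans
  } else { # observer
    series <- if (p$target_player == 1L) p$history$p1 else p$history$p2
    ans <- extrapolate(series)
    if (is.null(ans)) stop2("contract", "observer prompt carries no history")
    ans
  }
}

# parse a rendered prompt back into structured form; shared by all mock
# personas, so any template drift surfaces as a contract error in tests
parse_prompt_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]

  query <- if (any(grepl("Which option do you choose", lines))) "choose"
    else if (any(grepl("do you predict the other player", lines))) "predict"
    else if (any(grepl("Which option will player", lines))) "observe"
    else stop2("contract", "prompt has no recognizable query")

  qline <- lines[length(lines)]
  m <- regmatches(qline, regexec("Option (\\w+) or Option (\\w+)\\? A: Option$", qline))[[1]]
  if (length(m) != 3L) stop2("contract", "query line does not offer two option tokens")
  options <- m[2:3]

  m <- regmatches(qline, regexec("round (\\d+)", qline))[[1]]
  round <- if (length(m) == 2L) as.integer(m[2]) else NA_integer_
  target_player <- NA_integer_
  if (query == "observe") {
    m <- regmatches(qline, regexec("will player (\\d) choose", qline))[[1]]
    target_player <- as.integer(m[2])
  }

  rules_re <- "^If you choose Option (\\w+) and the other player chooses Option (\\w+), then you win ([-0-9.]+) \\w+ and the other player wins ([-0-9.]+) \\w+\\.$"
  rl <- regmatches(lines, regexec(rules_re, lines))
  rl <- rl[lengths(rl) == 5L]
  rules <- if (length(rl)) {
    data.frame(own = vapply(rl, `[`, "", 2L), other = vapply(rl, `[`, "", 3L),
               own_pay = as.numeric(vapply(rl, `[`, "", 4L)),
               other_pay = as.numeric(vapply(rl, `[`, "", 5L)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(own = character(0), other = character(0),
               own_pay = numeric(0), other_pay = numeric(0))
  }

  hist_you_re <- "^In round (\\d+), you chose Option (\\w+) and the other player chose Option (\\w+)\\."
  hist_obs_re <- "^In round (\\d+), player 1 chose Option (\\w+) and player 2 chose Option (\\w+)\\."
  hy <- regmatches(lines, regexec(hist_you_re, lines)); hy <- hy[lengths(hy) == 4L]
  ho <- regmatches(lines, regexec(hist_obs_re, lines)); ho <- ho[lengths(ho) == 4L]
  if (length(hy)) {
    history <- data.frame(round = as.integer(vapply(hy, `[`, "", 2L)),
                          own = vapply(hy, `[`, "", 3L),
                          other = vapply(hy, `[`, "", 4L), stringsAsFactors = FALSE)
  } else if (length(ho)) {
    history <- data.frame(round = as.integer(vapply(ho, `[`, "", 2L)),
                          p1 = vapply(ho, `[`, "", 3L),
                          p2 = vapply(ho, `[`, "", 4L), stringsAsFactors = FALSE)
    # "other" from the queried player's opponent viewpoint is not defined
    # in observer mode; personas use p1/p2 directly
    history$own <- history$p1
    history$other <- history$p2
  } else if (any(lines == "This is the first round.")) {
    history <- data.frame(round = integer(0), own = character(0),
                          other = character(0), stringsAsFactors = FALSE)
  } else {
    stop2("contract", "prompt has no parsable history section")
  }

  pm <- regmatches(lines, regexec(
    "^You predict that the other player will choose Option (\\w+) in this round\\.$", lines))
  pm <- pm[lengths(pm) == 2L]
  prediction <- if (length(pm)) pm[[1]][2] else NULL

  list(query = query, options = options, round = round,
       target_player = target_player, rules = rules, history = history,
       prediction = prediction)
}
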