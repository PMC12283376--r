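#' Prompt framing variants
#'
#' A `prompt_variant` bundles every framing knob of the textual game
#' interface that the robustness checks vary: the option tokens, the order
#' in which options are presented, the name of the utility unit, an optional
#' cover story, the disclosed horizon, and intervention flags. Variants
#' change framing only — never the pay-offs.
#'
#' @param config A list with any of the fields:
#'   * `option_labels` — `"neutral"` (the default `F`/`J`), `"random"`
#'     (two distinct letters drawn from a fixed pool of letters of similar
#'     frequency in English), or a character vector of two distinct
#'     single-letter tokens.
#'   * `label_order` — `"as_declared"` (default) or `"swapped"`:
#'     presentation order of the options in the prompt text.
#'   * `utility` — `"points"` (default), `"dollars"` or `"coins"`.
#'   * `cover_story` — `NULL` (default), `"cooking_competition"` or
#'     `"collaborative_project"`.
#'   * `horizon_disclosed` — number of rounds the prompt announces
#'     (default 10).
#'   * `fallibility_notice` — add a sentence that the other player
#'     sometimes makes mistakes (default `FALSE`).
#'   * `opponent_info` — `NULL`, or free text describing the opponent's
#'     strategy, inserted verbatim (the explicit-opponent-information
#'     intervention).
#'   * `explicit_end_goal` — add an explicit score-maximization goal
#'     sentence (default `FALSE`).
#' @param seed Integer seed driving the random label draw; required when
#'   `option_labels = "random"` so every randomization is replayable.
#'
#' @return An object of class `prompt_variant`.
#' @examples
#' make_variant() # neutral F/J, points
#' make_variant(list(option_labels = "random", utility = "coins"), seed = 11)
#' @export
make_variant <- function(config = list(), seed = NULL) {
  known <- c("option_labels", "label_order", "utility", "cover_story",
             "horizon_disclosed", "fallibility_notice", "opponent_info",
             "explicit_end_goal")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop2("validation", sprintf("unknown variant field(s): %s", paste(bad, collapse = ", ")))
  }
  labels <- config$option_labels %||% "neutral"
  if (identical(labels, "neutral")) {
    labels <- c("F", "J")
  } else if (identical(labels, "random")) {
    if (is.null(seed)) stop2("validation", "random labels need a `seed`")
    labels <- local_seed(seed, sample(letter_pool(), 2L))
  }
  if (!is.character(labels) || length(labels) != 2L || anyDuplicated(labels) ||
      !all(grepl("^[A-Za-z]$", labels))) {
    stop2("validation", "option labels must be two distinct single-letter tokens")
  }
  order <- config$label_order %||% "as_declared"
  if (!order %in% c("as_declared", "swapped")) {
    stop2("validation", "`label_order` must be 'as_declared' or 'swapped'")
  }
  utility <- config$utility %||% "points"
  if (!utility %in% c("points", "dollars", "coins")) {
    stop2("validation", sprintf("unknown utility name '%s' (points, dollars or coins)", utility))
  }
  story <- config$cover_story
  if (!is.null(story) && !story %in% names(cover_stories())) {
    stop2("validation", sprintf("unknown cover story '%s' (available: %s)",
                                story, paste(names(cover_stories()), collapse = ", ")))
  }
  horizon <- config$horizon_disclosed %||% 10L
  if (!is.null(horizon) && (!is.numeric(horizon) || horizon < 1)) {
    stop2("validation", "`horizon_disclosed` must be >= 1 (or NULL to suppress)")
  }
  structure(
    list(
      option_labels = unname(labels),
      label_order = order,
      utility = utility,
      cover_story = story,
      horizon_disclosed = if (is.null(horizon)) NULL else as.integer(horizon),
      fallibility_notice = isTRUE(config$fallibility_notice),
      opponent_info = config$opponent_info,
      explicit_end_goal = isTRUE(config$explicit_end_goal),
      seed = seed
    ),
    class = "prompt_variant"
  )
}

# letters of broadly similar, moderate frequency in English text
letter_pool <- function() c("B", "C", "F", "G", "J", "K", "M", "P", "V", "W")

cover_stories <- function() {
  c(cooking_competition =
      "Imagine you are taking part in a cooking competition together with another contestant.",
    collaborative_project =
      "Imagine you are working on a collaborative project together with a colleague.")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# run code under a fixed seed without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# tokens the variant assigns to a player's options, in declared option order
variant_tokens <- function(matrix, role, variant) {
  if (is.null(variant$option_labels)) player_options(matrix, role)
  else variant$option_labels
}

# presentation order of option indices
presentation_order <- function(variant) {
  if (identical(variant$label_order, "swapped")) c(2L, 1L) else c(1L, 2L)
}

#' Render the textual rules of a game
#'
#' Turns a pay-off matrix into deterministic natural-language game rules:
#' one clause per joint choice stating both players' pay-offs in the
#' variant's utility units, options presented in the variant's order.
#'
#' @param matrix A [payoff_matrix()].
#' @param variant A [make_variant()] object.
#' @param perspective `"player"` (second person, from `role`'s seat) or
#'   `"observer"` (third person, for the observer prediction mode).
#' @param role Seat of the addressed player (ignored for observer).
#' @return A single string.
#' @export
render_rules <- function(matrix, variant = make_variant(),
                         perspective = c("player", "observer"), role = 1L) {
  perspective <- match.arg(perspective)
  own <- variant_tokens(matrix, role, variant)
  other <- variant_tokens(matrix, 3L - role, variant)
  ord <- presentation_order(variant)
  unit <- variant$utility

  lines <- character(0)
  if (!is.null(variant$cover_story)) {
    lines <- c(lines, unname(cover_stories()[variant$cover_story]))
  }
  horizon <- if (is.null(variant$horizon_disclosed)) "" else
    sprintf(" You will play %d rounds in total with the same player.",
            variant$horizon_disclosed)
  if (perspective == "player") {
    lines <- c(lines, sprintf(
      "You are playing a game repeatedly with another player. In this game, you can choose between Option %s and Option %s.%s",
      own[ord[1]], own[ord[2]], horizon))
    if (variant$fallibility_notice) {
      lines <- c(lines,
        "Keep in mind that the other player sometimes makes mistakes and may not play the option they intended.")
    }
    if (!is.null(variant$opponent_info)) lines <- c(lines, variant$opponent_info)
    if (variant$explicit_end_goal) {
      lines <- c(lines, sprintf("Your goal is to win as many %s as possible over all rounds.", unit))
    }
    lines <- c(lines, "The rules of the game are as follows:")
    for (i in ord) {
      for (j in ord) {
        pay <- if (role == 1L) c(matrix$p1[i, j], matrix$p2[i, j])
               else c(matrix$p2[j, i], matrix$p1[j, i])
        lines <- c(lines, sprintf(
          "If you choose Option %s and the other player chooses Option %s, then you win %g %s and the other player wins %g %s.",
          own[i], other[j], pay[1], unit, pay[2], unit))
      }
    }
  } else {
    t1 <- variant_tokens(matrix, 1L, variant)
    t2 <- variant_tokens(matrix, 2L, variant)
    h <- if (is.null(variant$horizon_disclosed)) "" else
      sprintf(" They will play %d rounds in total.", variant$horizon_disclosed)
    lines <- c(lines, sprintf(
      "Two players, player 1 and player 2, are playing a game repeatedly. In this game, each player can choose between Option %s and Option %s.%s",
      t1[ord[1]], t1[ord[2]], h))
    lines <- c(lines, "The rules of the game are as follows:")
    for (i in ord) {
      for (j in ord) {
        lines <- c(lines, sprintf(
          "If player 1 chooses Option %s and player 2 chooses Option %s, then player 1 wins %g %s and player 2 wins %g %s.",
          t1[i], t2[j], matrix$p1[i, j], unit, matrix$p2[i, j], unit))
      }
    }
  }
  paste(lines, collapse = "\n")
}

#' Render the game history block
#'
#' One line per completed round, from the given player's perspective
#' (second person) or an observer's (third person), stating both choices
#' and both scores. An empty transcript renders a first-round marker.
#'
#' @param transcript A [play_match()] transcript (may have zero rounds).
#' @param role Perspective seat, 1 or 2.
#' @param variant A [make_variant()] object (controls tokens and units).
#' @param perspective `"player"` or `"observer"`.
#' @param cumulative Also report running totals? Default `FALSE`.
#' @return A single string.
#' @export
render_history <- function(transcript, role, variant = make_variant(),
                           perspective = c("player", "observer"),
                           cumulative = FALSE) {
  perspective <- match.arg(perspective)
  if (!role %in% 1:2) stop2("validation", "`role` must be 1 or 2")
  rounds <- transcript$rounds
  unit <- variant$utility
  matrix <- transcript$matrix
  if (length(rounds) == 0L) return("This is the first round.")
  tok <- function(r, action) {
    variant_tokens(matrix, r, variant)[option_index(matrix, r, action)]
  }
  tot <- c(0, 0)
  lines <- vapply(rounds, function(rec) {
    a <- c(tok(1L, rec$action_p1), tok(2L, rec$action_p2))
    p <- c(rec$payoff_p1, rec$payoff_p2)
    tot <<- tot + p
    if (perspective == "player") {
      own <- role; oth <- 3L - role
      line <- sprintf(
        "In round %d, you chose Option %s and the other player chose Option %s. You won %g %s and the other player won %g %s.",
        rec$round, a[own], a[oth], p[own], unit, p[oth], unit)
      if (cumulative) line <- paste(line, sprintf(
        "In total, you have won %g %s and the other player has won %g %s.",
        tot[own], unit, tot[oth], unit))
    } else {
      line <- sprintf(
        "In round %d, player 1 chose Option %s and player 2 chose Option %s. Player 1 won %g %s and player 2 won %g %s.",
        rec$round, a[1], a[2], p[1], unit, p[2], unit)
      if (cumulative) line <- paste(line, sprintf(
        "In total, player 1 has won %g %s and player 2 has won %g %s.",
        tot[1], unit, tot[2], unit))
    }
    line
  }, character(1))
  paste(lines, collapse = "\n")
}

#' Assemble a full prompt
#'
#' Concatenates rules, history and a query into the context string passed
#' to a text backend, and reports which tokens constitute valid answers.
#'
#' @inheritParams render_history
#' @param matrix A [payoff_matrix()].
#' @param query_kind `"choose"` (ask for the agent's own next move),
#'   `"predict_opponent"` (ask the playing agent for the other player's
#'   next move) or `"observe_predict"` (frame the agent as a mere observer
#'   of two external players and ask for `target_player`'s next move; the
#'   transcript must then contain at least one completed round).
#' @param prediction Optional option token: when given with
#'   `query_kind = "choose"`, a line announcing the agent's own prediction
#'   of the opponent's move is inserted before the query (the social
#'   chain-of-thought second stage).
#' @param target_player Player whose move is queried in observer mode.
#' @return An object of class `rendered_prompt`: a list with `text`,
#'   `option_tokens` (valid answer tokens, in presentation order) and
#'   `query_kind`.
#' @export
build_prompt <- function(matrix, transcript, role, variant = make_variant(),
                         query_kind = c("choose", "predict_opponent", "observe_predict"),
                         prediction = NULL, target_player = 2L) {
  query_kind <- match.arg(query_kind)
  n_done <- length(transcript$rounds)
  current <- n_done + 1L
  ord <- presentation_order(variant)

  if (query_kind == "observe_predict") {
    if (n_done < 1L) {
      stop2("validation", "observer prediction needs at least one completed round")
    }
    toks <- variant_tokens(matrix, target_player, variant)
    parts <- c(
      render_rules(matrix, variant, "observer"),
      render_history(transcript, role = 1L, variant, "observer"),
      sprintf(
        "The players are currently playing round %d. Q: Which option will player %d choose in this round, Option %s or Option %s? A: Option",
        current, target_player, toks[ord[1]], toks[ord[2]])
    )
    toks_q <- toks
  } else {
    toks_q <- variant_tokens(matrix, role, variant)
    other_toks <- variant_tokens(matrix, 3L - role, variant)
    query <- switch(query_kind,
      choose = sprintf(
        "You are currently playing round %d. Q: Which option do you choose, Option %s or Option %s? A: Option",
        current, toks_q[ord[1]], toks_q[ord[2]]),
      predict_opponent = sprintf(
        "You are currently playing round %d. Q: Which option do you predict the other player will choose in this round, Option %s or Option %s? A: Option",
        current, other_toks[ord[1]], other_toks[ord[2]])
    )
    parts <- c(
      render_rules(matrix, variant, "player", role),
      render_history(transcript, role, variant, "player")
    )
    if (!is.null(prediction) && query_kind == "choose") {
      parts <- c(parts, sprintf(
        "You predict that the other player will choose Option %s in this round.",
        prediction))
    }
    parts <- c(parts, query)
    if (query_kind == "predict_opponent") toks_q <- other_toks
  }
  structure(
    list(text = paste(parts, collapse = "\n"),
         option_tokens = toks_q[ord],
         query_kind = query_kind),
    class = "rendered_prompt"
  )
}

#' @export
print.rendered_prompt <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}
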