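#' Decision policies
#'
#' An `agent_policy` maps `(matrix, role, history, variant)` to one of the
#' player's declared options. Policies are deterministic; `reset` (if
#' given) clears any internal state between matches.
#'
#' @param name Identifier used in transcripts and reports.
#' @param decide Function `(matrix, role, transcript, variant)` returning
#'   an option label, or a list with fields `action` and optionally
#'   `prediction` and `distribution`.
#' @param reset Optional zero-argument function clearing internal state.
#' @return An object of class `agent_policy`.
#' @export
agent_policy <- function(name, decide, reset = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.function(decide))
  structure(list(name = name, decide = decide, reset = reset),
            class = "agent_policy")
}

#' @export
print.agent_policy <- function(x, ...) {
  cat("agent policy:", x$name, "\n")
  invisible(x)
}

# label of the option filling a semantic action role (cooperate/defect)
role_label <- function(matrix, role, what) {
  idx <- matrix$action_roles[[what]]
  if (is.null(idx)) {
    stop2("validation", sprintf(
      "the game does not declare a '%s' option (no `action_roles` metadata)", what))
  }
  player_options(matrix, role)[idx]
}

#' Scripted human-like strategies
#'
#' Deterministic benchmark strategies:
#'
#' * `always_option` — always plays `option` (a label or an index 1/2).
#' * `always_cooperate` / `always_defect` — singleton players keyed on the
#'   game's cooperate/defect roles.
#' * `false_defector` — defects in round 1, cooperates in every round
#'   thereafter (probes whether an opponent rebuilds trust).
#' * `grim_trigger` — cooperates until the opponent's first observed
#'   defection, then defects forever (the unforgiving signature).
#' * `alternator` — turn-taking: starts, for courtesy, with the option the
#'   other player prefers and switches option every round (the convention
#'   human players often converge to in Battle-of-the-Sexes-like games).
#' * `stubborn_preferred` — always plays its own preferred option, i.e.
#'   the option indexing its maximum pay-off cell.
#'
#' All strategies are pure functions of the round number and the opponent's
#' observed history; none keeps hidden state.
#'
#' @param kind One of the strategy names above.
#' @param option For `always_option`: the option to play (label or index).
#' @param name Agent name; defaults to `kind`.
#' @return An [agent_policy()].
#' @examples
#' scripted_agent("false_defector")
#' scripted_agent("always_option", option = "F")
#' @export
scripted_agent <- function(kind = c("always_option", "always_cooperate",
                                    "always_defect", "false_defector",
                                    "grim_trigger", "alternator",
                                    "stubborn_preferred"),
                           option = NULL, name = NULL) {
  kind <- match.arg(kind)
  if (kind == "always_option" && is.null(option)) {
    stop2("validation", "`always_option` needs an `option` parameter")
  }
  decide <- switch(kind,
    always_option = function(matrix, role, transcript, variant) {
      player_options(matrix, role)[option_index(matrix, role, option)]
    },
    always_cooperate = function(matrix, role, transcript, variant) {
      role_label(matrix, role, "cooperate")
    },
    always_defect = function(matrix, role, transcript, variant) {
      role_label(matrix, role, "defect")
    },
    false_defector = function(matrix, role, transcript, variant) {
      first <- length(transcript$rounds) == 0L
      role_label(matrix, role, if (first) "defect" else "cooperate")
    },
    grim_trigger = function(matrix, role, transcript, variant) {
      opp <- 3L - role
      opp_defect <- role_label(matrix, opp, "defect")
      betrayed <- any(vapply(transcript$rounds, function(r) {
        r[[paste0("action_p", opp)]] == opp_defect
      }, logical(1)))
      role_label(matrix, role, if (betrayed) "defect" else "cooperate")
    },
    alternator = function(matrix, role, transcript, variant) {
      opp <- 3L - role
      start <- match(preferred_option(matrix, opp), player_options(matrix, opp))
      t <- length(transcript$rounds) + 1L
      idx <- if (t %% 2L == 1L) start else 3L - start
      player_options(matrix, role)[idx]
    },
    stubborn_preferred = function(matrix, role, transcript, variant) {
      preferred_option(matrix, role)
    }
  )
  agent_policy(name %||% if (kind == "always_option")
    paste0("always_", option) else kind, decide)
}

#' Argmax option choice from a next-token distribution
#'
#' Restricts a backend's next-token distribution to the two valid option
#' tokens and returns the one with the larger mass. Mass on any other token
#' is ignored. An exact tie is broken towards the first declared token,
#' with a warning (a total order is required for reproducible play at
#' temperature 0).
#'
#' @param distribution Named numeric vector: token -> probability mass.
#' @param option_tokens Character vector of the two valid answer tokens,
#'   in declared order.
#' @return The chosen token.
#' @export
parse_choice <- function(distribution, option_tokens) {
  if (is.null(names(distribution)) || length(distribution) == 0L) {
    stop2("unparseable", "token distribution must be a non-empty named vector")
  }
  if (any(distribution < 0)) {
    stop2("validation", "token probabilities must be non-negative")
  }
  mass <- vapply(option_tokens, function(tk) {
    if (tk %in% names(distribution)) distribution[[tk]] else NA_real_
  }, numeric(1))
  if (all(is.na(mass))) {
    stop2("unparseable", sprintf(
      "neither option token (%s) received any probability mass",
      paste(option_tokens, collapse = ", ")))
  }
  mass[is.na(mass)] <- 0
  if (mass[1] == mass[2]) {
    warning(sprintf("tie between option tokens %s and %s; choosing the first declared",
                    option_tokens[1], option_tokens[2]))
    return(option_tokens[1])
  }
  option_tokens[which.max(mass)]
}

#' Text completion backends
#'
#' A `text_backend` wraps a completion endpoint behind a minimal contract:
#' prompt text in, named token-probability vector out. At temperature 0 a
#' backend must be deterministic per prompt. The offline [mock_backend()]
#' implements this contract; adapters for hosted APIs can too.
#'
#' @param complete Function `(prompt_text) -> named numeric vector` of
#'   next-token probability masses.
#' @param temperature Sampling temperature (only 0 is exercised).
#' @param description Identifier.
#' @return An object of class `text_backend`.
#' @export
text_backend <- function(complete, temperature = 0, description = "backend") {
  stopifnot(is.function(complete))
  structure(list(complete = complete, temperature = temperature,
                 description = description),
            class = "text_backend")
}

# query with up to 3 retries on transport failures; unparseable answers are
# never retried (they are a property of the model, not of the transport)
backend_complete <- function(backend, text, retries = 3L) {
  for (attempt in seq_len(retries)) {
    res <- tryCatch(backend$complete(text),
                    games2x2_transport_error = function(e) e)
    if (!inherits(res, "games2x2_transport_error")) return(res)
    if (attempt == retries) stop(res)
  }
}

# map a chosen prompt token back to the matrix's own option label
token_to_label <- function(matrix, role, variant, token) {
  idx <- match(token, variant_tokens(matrix, role, variant))
  if (is.na(idx)) {
    stop2("unparseable", sprintf("token '%s' is not an option token of player %d", token, role))
  }
  player_options(matrix, role)[idx]
}

#' Text-completion-backed agent
#'
#' Wraps a [text_backend()] as an [agent_policy()]: each round it renders a
#' choose prompt from the pay-off matrix, history and variant, queries the
#' backend once for the next-token distribution, and takes the argmax over
#' the two option tokens ([parse_choice()]). The raw distribution is
#' recorded in the transcript round.
#'
#' @param backend A [text_backend()].
#' @param name Agent name (default: the backend description).
#' @return An [agent_policy()].
#' @export
text_agent <- function(backend, name = backend$description) {
  agent_policy(name, function(matrix, role, transcript, variant) {
    text_agent_decide(backend, matrix, role, transcript, variant)
  })
}

#' One choose-query decision through a text backend
#'
#' @inheritParams text_agent
#' @param matrix A [payoff_matrix()].
#' @param role Seat, 1 or 2.
#' @param transcript History so far.
#' @param variant A [make_variant()] object.
#' @return A list with `action` (matrix option label) and `distribution`.
#' @export
text_agent_decide <- function(backend, matrix, role, transcript,
                              variant = make_variant()) {
  prompt <- build_prompt(matrix, transcript, role, variant, "choose")
  dist <- backend_complete(backend, prompt$text)
  token <- parse_choice(dist, prompt$option_tokens)
  list(action = token_to_label(matrix, role, variant, token),
       distribution = dist)
}

#' Social chain-of-thought agent
#'
#' Two-stage prompting: the agent is first asked to predict the opponent's
#' next move; its own choose prompt is then augmented with the stated
#' prediction so that the choice can reason about it. Both the prediction
#' and the action are recorded in the transcript round. An unparseable
#' prediction aborts the decision before any action is emitted.
#'
#' @inheritParams text_agent
#' @return An [agent_policy()].
#' @export
scot_agent <- function(backend, name = paste0(backend$description, "_scot")) {
  agent_policy(name, function(matrix, role, transcript, variant) {
    scot_decide(backend, matrix, role, transcript, variant)
  })
}

#' @rdname scot_agent
#' @inheritParams text_agent_decide
#' @return For `scot_decide`: a list with `action`, `prediction`
#'   (`list(round, predicted, actual)`, `actual` filled by the engine) and
#'   `distribution`.
#' @export
scot_decide <- function(backend, matrix, role, transcript,
                        variant = make_variant()) {
  opp <- 3L - role
  p_pred <- build_prompt(matrix, transcript, role, variant, "predict_opponent")
  d_pred <- backend_complete(backend, p_pred$text)
  pred_token <- parse_choice(d_pred, p_pred$option_tokens)

  p_act <- build_prompt(matrix, transcript, role, variant, "choose",
                        prediction = pred_token)
  d_act <- backend_complete(backend, p_act$text)
  act_token <- parse_choice(d_act, p_act$option_tokens)

  list(
    action = token_to_label(matrix, role, variant, act_token),
    prediction = list(round = length(transcript$rounds) + 1L,
                      predicted = token_to_label(matrix, opp, variant, pred_token),
                      actual = NA_character_),
    distribution = d_act
  )
}

#' Observer-mode prediction
#'
#' Frames the backend as a mere observer of a game between two external
#' players and asks it to predict the designated player's next move from
#' the shown history. The transcript must contain at least one completed
#' round.
#'
#' @inheritParams text_agent_decide
#' @param target_player Player (1 or 2) whose next move is queried.
#' @return A list with `round`, `predicted` (matrix option label) and
#'   `actual` (`NA`; fill in once the move is known).
#' @export
observer_predict <- function(backend, matrix, transcript,
                             variant = make_variant(), target_player = 2L) {
  prompt <- build_prompt(matrix, transcript, role = 1L, variant,
                         "observe_predict", target_player = target_player)
  dist <- backend_complete(backend, prompt$text)
  token <- parse_choice(dist, prompt$option_tokens)
  list(round = length(transcript$rounds) + 1L,
       predicted = token_to_label(matrix, target_player, variant, token),
       actual = NA_character_)
}
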