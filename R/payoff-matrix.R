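#' Construct a 2x2 pay-off matrix
#'
#' A `payoff_matrix` holds both players' pay-offs for every joint choice in a
#' two-player, two-action simultaneous game. Rows index player 1's options,
#' columns player 2's options.
#'
#' @param cells A list of four pay-off pairs in row-major order
#'   (`(o1,o1), (o1,o2), (o2,o1), (o2,o2)`), each a numeric vector
#'   `c(p1, p2)`; alternatively a list with elements `p1` and `p2`, each a
#'   2x2 numeric matrix.
#' @param options_p1,options_p2 Character vectors of length 2: the option
#'   labels for each player. Labels must be distinct within a player.
#' @param action_roles Optional named list mapping semantic action roles
#'   (e.g. `cooperate`, `defect`) to option indices (1 or 2), assumed the
#'   same for both players. Used by strategies and metrics that are defined
#'   in terms of cooperation/defection rather than raw labels.
#'
#' @return An object of class `payoff_matrix` with components `p1` and `p2`
#'   (2x2 numeric matrices, `dimnames` set to the option labels),
#'   `options_p1`, `options_p2` and `action_roles`.
#' @examples
#' pd <- payoff_matrix(
#'   cells = list(c(8, 8), c(0, 10), c(10, 0), c(5, 5)),
#'   options_p1 = c("Cooperate", "Defect"),
#'   options_p2 = c("Cooperate", "Defect")
#' )
#' payoff_at(pd, "Defect", "Cooperate") # c(10, 0)
#' @export
payoff_matrix <- function(cells, options_p1 = c("F", "J"),
                          options_p2 = options_p1, action_roles = NULL) {
  if (is.list(cells) && !is.null(cells$p1)) {
    p1 <- cells$p1
    p2 <- cells$p2
  } else {
    if (!is.list(cells) || length(cells) != 4L) {
      stop2("validation", "`cells` must be a list of 4 pay-off pairs (2x2 grid, row-major)")
    }
    ok <- vapply(cells, function(x) is.numeric(x) && length(x) == 2L, logical(1))
    if (!all(ok)) {
      stop2("validation", "every cell must be a numeric pair c(p1, p2)")
    }
    p1 <- matrix(vapply(cells, `[`, numeric(1), 1L), 2, 2, byrow = TRUE)
    p2 <- matrix(vapply(cells, `[`, numeric(1), 2L), 2, 2, byrow = TRUE)
  }
  if (!is.matrix(p1) || !identical(dim(p1), c(2L, 2L)) ||
      !is.matrix(p2) || !identical(dim(p2), c(2L, 2L))) {
    stop2("validation", "pay-off grids must be 2x2")
  }
  if (!all(is.finite(p1)) || !all(is.finite(p2))) {
    stop2("validation", "all pay-offs must be finite")
  }
  check_labels <- function(x, who) {
    if (!is.character(x) || length(x) != 2L || anyDuplicated(x) || any(!nzchar(x))) {
      stop2("validation", sprintf("`%s` must be two distinct non-empty labels", who))
    }
  }
  check_labels(options_p1, "options_p1")
  check_labels(options_p2, "options_p2")
  if (!is.null(action_roles)) {
    if (!all(unlist(action_roles) %in% 1:2) || is.null(names(action_roles))) {
      stop2("validation", "`action_roles` must be a named list of option indices in 1:2")
    }
  }
  dimnames(p1) <- dimnames(p2) <- list(options_p1, options_p2)
  structure(
    list(p1 = p1, p2 = p2, options_p1 = options_p1, options_p2 = options_p2,
         action_roles = action_roles),
    class = "payoff_matrix"
  )
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("2x2 pay-off matrix (rows: player 1, columns: player 2)\n")
  disp <- matrix(
    sprintf("(%g, %g)", x$p1, x$p2), 2, 2,
    dimnames = list(x$options_p1, x$options_p2)
  )
  print(disp, quote = FALSE)
  invisible(x)
}

#' Look up the pay-off pair for a joint choice
#'
#' @param matrix A [payoff_matrix()].
#' @param a1,a2 Option labels (or indices 1/2) chosen by players 1 and 2.
#' @return Numeric vector `c(p1, p2)`.
#' @export
payoff_at <- function(matrix, a1, a2) {
  i <- option_index(matrix, 1L, a1)
  j <- option_index(matrix, 2L, a2)
  c(matrix$p1[i, j], matrix$p2[i, j])
}

# resolve a label or index to an option index for a given player
option_index <- function(matrix, role, action) {
  opts <- player_options(matrix, role)
  if (is.numeric(action) && action %in% 1:2) return(as.integer(action))
  i <- match(action, opts)
  if (is.na(i)) {
    stop2("protocol", sprintf("'%s' is not an option of player %d (options: %s)",
                              action, role, paste(opts, collapse = ", ")))
  }
  i
}

#' Options of one player
#' @inheritParams payoff_at
#' @param role Player seat, 1 or 2.
#' @return Character vector of length 2.
#' @export
player_options <- function(matrix, role) {
  if (role == 1) matrix$options_p1 else matrix$options_p2
}

# that player's pay-off grid oriented so that rows are the player's own
# options and columns the opponent's
own_payoffs <- function(matrix, role) {
  if (role == 1) matrix$p1 else t(matrix$p2)
}

#' Option a player likes best
#'
#' The player's preferred option is the one indexing the cell holding that
#' player's maximum pay-off (used, e.g., by the stubborn strategy and by the
#' alternating strategy's courtesy start).
#'
#' @inheritParams player_options
#' @return The preferred option's label.
#' @export
preferred_option <- function(matrix, role) {
  m <- own_payoffs(matrix, role)
  best <- which(m == max(m), arr.ind = TRUE)
  player_options(matrix, role)[best[1, 1]]
}

#' Built-in canonical games
#'
#' Returns one of the two canonical pay-off matrices used throughout:
#' the Prisoner's Dilemma
#' \deqn{\begin{array}{ccc} & C & D \\ C & (8,8) & (0,10) \\ D & (10,0) & (5,5)\end{array}}
#' and the Battle of the Sexes
#' \deqn{\begin{array}{ccc} & F & B \\ F & (10,7) & (0,0) \\ B & (0,0) & (7,10)\end{array}}
#'
#' By default the options carry the neutral single-letter labels `F` and `J`
#' (first and second declared option for both players), which avoids priming
#' text-backed agents with loaded words; `neutral_labels = FALSE` keeps the
#' descriptive labels (Cooperate/Defect, Football/Ballet).
#'
#' @param name `"prisoners_dilemma"` or `"battle_of_the_sexes"`.
#' @param neutral_labels Replace descriptive labels by `F`/`J`? Default `TRUE`.
#' @return A [payoff_matrix()]. For the Prisoner's Dilemma, `action_roles`
#'   marks which option is Cooperate and which is Defect so strategies and
#'   metrics keyed on those roles work under any labelling.
#' @export
canonical_game <- function(name = c("prisoners_dilemma", "battle_of_the_sexes"),
                           neutral_labels = TRUE) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("prisoners_dilemma", "battle_of_the_sexes")) {
    stop2("lookup", sprintf(
      "unknown canonical game '%s' (available: prisoners_dilemma, battle_of_the_sexes)",
      paste(name, collapse = "/")))
  }
  switch(name,
    prisoners_dilemma = payoff_matrix(
      cells = list(c(8, 8), c(0, 10), c(10, 0), c(5, 5)),
      options_p1 = if (neutral_labels) c("F", "J") else c("Cooperate", "Defect"),
      options_p2 = if (neutral_labels) c("F", "J") else c("Cooperate", "Defect"),
      action_roles = list(cooperate = 1L, defect = 2L)
    ),
    battle_of_the_sexes = payoff_matrix(
      cells = list(c(10, 7), c(0, 0), c(0, 0), c(7, 10)),
      options_p1 = if (neutral_labels) c("F", "J") else c("Football", "Ballet"),
      options_p2 = if (neutral_labels) c("F", "J") else c("Football", "Ballet")
    )
  )
}

#' Best achievable total over a repeated game
#'
#' The score a player would reach if every round ended in that player's best
#' cell: `rounds * max(player's four pay-offs)`. This is the denominator of
#' the normalized tournament score ("ideal conditions").
#'
#' @inheritParams player_options
#' @param rounds Number of repetitions (>= 1).
#' @return A single number.
#' @export
max_ideal_score <- function(matrix, role, rounds) {
  if (!is.numeric(rounds) || length(rounds) != 1L || rounds < 1 ||
      rounds != round(rounds)) {
    stop2("validation", "`rounds` must be a whole number >= 1")
  }
  rounds * max(own_payoffs(matrix, role))
}

#' Read a game definition file
#'
#' Reads a YAML (or JSON) file with fields `options_p1`, `options_p2` and
#' `cells` (row-major list of `[p1, p2]` pairs) into a validated
#' [payoff_matrix()]. An optional `action_roles` mapping is honoured.
#'
#' @param path Path to the definition file.
#' @return A [payoff_matrix()].
#' @export
read_game <- function(path) {
  if (!file.exists(path)) stop2("validation", sprintf("no such file: %s", path))
  def <- yaml::read_yaml(path)
  for (f in c("options_p1", "options_p2", "cells")) {
    if (is.null(def[[f]])) stop2("validation", sprintf("game file missing field '%s'", f))
  }
  cells <- lapply(def$cells, function(x) as.numeric(unlist(x)))
  roles <- def$action_roles
  if (!is.null(roles)) roles <- lapply(roles, as.integer)
  payoff_matrix(cells, as.character(def$options_p1), as.character(def$options_p2),
                action_roles = roles)
}

# classed conditions so callers can distinguish validation, lookup, protocol,
# parsing and transport failures
stop2 <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("games2x2_", class, "_error"), "games2x2_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}
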