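#' Strict ordinal 2x2 games
#'
#' An `ordinal_game` abstracts a pay-off matrix down to each player's
#' preference ranking over the four outcomes: rank 1 is that player's worst
#' outcome and rank 4 the best. Only strict games (no ties within a player)
#' have an ordinal form.
#'
#' @param ranks_p1,ranks_p2 2x2 integer matrices; each must contain a
#'   permutation of 1:4. Rows index player 1's options, columns player 2's.
#' @return An object of class `ordinal_game` with components `ranks_p1`,
#'   `ranks_p2` and `canonical_id` (the id of the game's canonical class
#'   under within-player option swaps).
#' @export
ordinal_game <- function(ranks_p1, ranks_p2) {
  chk <- function(m, who) {
    m <- matrix(as.integer(m), 2, 2)
    if (!identical(sort(as.integer(m)), 1:4)) {
      stop2("validation", sprintf("`%s` must be a 2x2 permutation of ranks 1..4", who))
    }
    m
  }
  g <- structure(
    list(ranks_p1 = chk(ranks_p1, "ranks_p1"), ranks_p2 = chk(ranks_p2, "ranks_p2")),
    class = "ordinal_game"
  )
  g$canonical_id <- ordinal_id(canonicalize(g))
  g
}

#' @export
print.ordinal_game <- function(x, ...) {
  cat("strict ordinal 2x2 game [", x$canonical_id, "]\n", sep = "")
  disp <- matrix(sprintf("(%d, %d)", x$ranks_p1, x$ranks_p2), 2, 2)
  print(disp, quote = FALSE)
  invisible(x)
}

ordinal_id <- function(g) {
  paste0("g", paste(c(t(g$ranks_p1), t(g$ranks_p2)), collapse = ""))
}

#' Ordinal abstraction of a numeric pay-off matrix
#'
#' Ranks each player's four pay-offs in ascending order (1 = worst,
#' 4 = best). Games with tied pay-offs within a player have no strict
#' ordinal form and raise a `games2x2_not_strict_error`.
#'
#' @param matrix A [payoff_matrix()].
#' @return An [ordinal_game()].
#' @examples
#' to_ordinal(canonical_game("prisoners_dilemma"))
#' @export
to_ordinal <- function(matrix) {
  rk <- function(m, who) {
    v <- as.numeric(m)
    if (anyDuplicated(v)) {
      stop2("not_strict", sprintf(
        "player %s has tied pay-offs; only strict games have an ordinal form", who))
    }
    matrix(rank(v), 2, 2)
  }
  ordinal_game(rk(matrix$p1, "1"), rk(matrix$p2, "2"))
}

#' Play an ordinal game by its ranks
#'
#' Lifts an [ordinal_game()] back to a playable [payoff_matrix()] with the
#' ranks 1..4 used as cardinal pay-offs. Because the normalized tournament
#' score only needs a per-player maximum, rank pay-offs suffice for
#' topology-wide tournaments.
#'
#' @param game An [ordinal_game()].
#' @param options_p1,options_p2 Option labels, default the neutral `F`/`J`.
#' @return A [payoff_matrix()].
#' @export
ordinal_payoffs <- function(game, options_p1 = c("F", "J"), options_p2 = options_p1) {
  payoff_matrix(list(p1 = game$ranks_p1 + 0, p2 = game$ranks_p2 + 0),
                options_p1, options_p2)
}

# the four symmetry transforms: identity, swap player-1's options (rows),
# swap player-2's options (columns), both. Player interchange is NOT part of
# the group: with it the topology would collapse to 78 classes.
apply_symmetry <- function(g, swap_rows, swap_cols) {
  r1 <- g$ranks_p1; r2 <- g$ranks_p2
  if (swap_rows) { r1 <- r1[2:1, , drop = FALSE]; r2 <- r2[2:1, , drop = FALSE] }
  if (swap_cols) { r1 <- r1[, 2:1, drop = FALSE]; r2 <- r2[, 2:1, drop = FALSE] }
  structure(list(ranks_p1 = r1, ranks_p2 = r2), class = "ordinal_game")
}

#' Canonical representative of a game's symmetry class
#'
#' Two strict ordinal games are equivalent if one arises from the other by
#' relabelling a player's two options (swapping rows and/or columns of both
#' rank grids). The canonical representative is the orbit member with the
#' lexicographically smallest id; canonicalization is idempotent.
#'
#' @param game An [ordinal_game()].
#' @return The canonical [ordinal_game()] of the same class.
#' @export
canonicalize <- function(game) {
  best <- NULL
  best_id <- NULL
  for (sr in c(FALSE, TRUE)) {
    for (sc in c(FALSE, TRUE)) {
      cand <- apply_symmetry(game, sr, sc)
      id <- ordinal_id(cand)
      if (is.null(best_id) || id < best_id) { best <- cand; best_id <- id }
    }
  }
  best$canonical_id <- best_id
  best
}

#' Enumerate the topology of strict ordinal 2x2 games
#'
#' Generates all \eqn{4! \times 4! = 576} strict rank assignments and
#' quotients them by the within-player option-swap group, yielding the 144
#' canonical classes of strict ordinal 2x2 games.
#'
#' @return A named list of 144 canonical [ordinal_game()] objects, keyed by
#'   `canonical_id`, in lexicographic id order.
#' @export
enumerate_games <- function() {
  perms <- rank_permutations()
  out <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(perms))) {
    r1 <- matrix(perms[i, ], 2, 2, byrow = TRUE)
    for (j in seq_len(nrow(perms))) {
      r2 <- matrix(perms[j, ], 2, 2, byrow = TRUE)
      g <- canonicalize(structure(list(ranks_p1 = r1, ranks_p2 = r2),
                                  class = "ordinal_game"))
      if (is.null(out[[g$canonical_id]])) out[[g$canonical_id]] <- g
    }
  }
  ids <- sort(ls(out))
  stats::setNames(lapply(ids, function(id) out[[id]]), ids)
}

# all 24 permutations of 1:4, one per row (reading order of the 2x2 grid)
rank_permutations <- function() {
  grid <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  grid[apply(grid, 1, function(r) length(unique(r)) == 4L), , drop = FALSE]
}

#' Pure-strategy Nash equilibria of a strict ordinal game
#'
#' A cell is a pure Nash equilibrium when neither player's rank improves by
#' unilaterally switching to their other option.
#'
#' @param game An [ordinal_game()].
#' @return A list of integer vectors `c(row, col)`, possibly empty.
#' @export
pure_nash <- function(game) {
  r1 <- game$ranks_p1; r2 <- game$ranks_p2
  out <- list()
  for (i in 1:2) {
    for (j in 1:2) {
      if (r1[i, j] > r1[3 - i, j] && r2[i, j] > r2[i, 3 - j]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  out
}

#' Dominant strategy of a player, if any
#'
#' An option is dominant when it is strictly better than the player's other
#' option against both opponent options.
#'
#' @param game An [ordinal_game()].
#' @param role Player seat, 1 or 2.
#' @return The dominant option's index (1 or 2), or `NA` if none.
#' @export
dominant_strategy <- function(game, role) {
  if (role == 1) {
    r <- game$ranks_p1
    for (i in 1:2) if (all(r[i, ] > r[3 - i, ])) return(i)
  } else {
    r <- game$ranks_p2
    for (j in 1:2) if (all(r[, j] > r[, 3 - j])) return(j)
  }
  NA_integer_
}

#' Classify a strict ordinal game into a structural family
#'
#' Assigns exactly one of six family labels (plus a residual) keyed on the
#' game's pure-Nash structure:
#'
#' * `cyclic` — no pure Nash equilibrium; play can cycle without settling.
#' * `win_win` — some cell gives both players their best outcome (4,4).
#' * `biased` — a Pareto-undominated equilibrium gives one player rank 4 and
#'   the other rank 3: coordination pays, but the players prefer different
#'   equilibria (Battle of the Sexes pattern).
#' * `unfair` — the best equilibria are (4,2)-shaped: one player wins
#'   outright while the other is held to a poor outcome.
#' * `second_best` — the best equilibrium gives both players their
#'   second-best outcome (3,3).
#' * `pd_family` — the remaining dilemmas: a low equilibrium ((2,2) or
#'   (2,3)-shaped) that is strictly Pareto-dominated by another cell, the
#'   Prisoner's Dilemma structure of individually rational but jointly
#'   suboptimal play.
#' * `unclassified` — low equilibrium with no strictly Pareto-superior cell
#'   (near-pure-conflict games); retained in the topology but outside the
#'   six families.
#'
#' Over the 144 canonical classes the families have sizes 18, 36, 44, 19,
#' 12, 7 and 8 respectively.
#'
#' @param game An [ordinal_game()].
#' @return A single character label.
#' @export
classify_family <- function(game) {
  ns <- pure_nash(game)
  if (length(ns) == 0L) return("cyclic")
  r1 <- game$ranks_p1; r2 <- game$ranks_p2
  if (any(r1 == 4 & r2 == 4)) return("win_win")

  best <- pareto_best_nash(game, ns)
  pairs <- vapply(best, function(cc) {
    paste(sort(c(r1[cc[1], cc[2]], r2[cc[1], cc[2]])), collapse = "")
  }, character(1))
  if (any(pairs == "34")) return("biased")
  if (any(pairs == "24")) return("unfair")
  if (any(pairs == "33")) return("second_best")

  # remaining equilibria are (2,2)- or (2,3)-shaped dilemmas
  eq <- best[[1L]]
  ep <- c(r1[eq[1], eq[2]], r2[eq[1], eq[2]])
  for (i in 1:2) {
    for (j in 1:2) {
      if (r1[i, j] > ep[1] && r2[i, j] > ep[2]) return("pd_family")
    }
  }
  "unclassified"
}

# Nash cells not Pareto-dominated by another Nash cell
pareto_best_nash <- function(game, ns = pure_nash(game)) {
  r1 <- game$ranks_p1; r2 <- game$ranks_p2
  pay <- lapply(ns, function(cc) c(r1[cc[1], cc[2]], r2[cc[1], cc[2]]))
  keep <- vapply(seq_along(ns), function(a) {
    !any(vapply(seq_along(ns), function(b) {
      b != a && all(pay[[b]] >= pay[[a]]) && any(pay[[b]] > pay[[a]])
    }, logical(1)))
  }, logical(1))
  ns[keep]
}

#' Tabulate the full topology with family labels
#'
#' @param games Optional precomputed result of [enumerate_games()].
#' @return A data frame with one row per canonical class: `canonical_id`,
#'   the eight rank entries (`p1_11` .. `p2_22`, row-major per player) and
#'   `family`. Suitable for CSV export.
#' @export
family_table <- function(games = enumerate_games()) {
  rows <- lapply(games, function(g) {
    data.frame(
      canonical_id = g$canonical_id,
      p1_11 = g$ranks_p1[1, 1], p1_12 = g$ranks_p1[1, 2],
      p1_21 = g$ranks_p1[2, 1], p1_22 = g$ranks_p1[2, 2],
      p2_11 = g$ranks_p2[1, 1], p2_12 = g$ranks_p2[1, 2],
      p2_21 = g$ranks_p2[2, 1], p2_22 = g$ranks_p2[2, 2],
      family = classify_family(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The six named game families
#'
#' @return Character vector of the six family labels, in the conventional
#'   reporting order (the residual `unclassified` label is not included).
#' @export
game_families <- function() {
  c("win_win", "pd_family", "unfair", "cyclic", "biased", "second_best")
}

#' Games of the six named families
#'
#' The canonical classes whose family is one of the six named families
#' (i.e. excluding the residual `unclassified` games), lifted to playable
#' rank-pay-off matrices. These 136 games form the default tournament set.
#'
#' @return A named list of [payoff_matrix()] objects keyed by canonical id;
#'   each carries its family label as attribute `"family"`.
#' @export
six_family_games <- function() {
  games <- enumerate_games()
  fams <- vapply(games, classify_family, character(1))
  keep <- names(games)[fams != "unclassified"]
  out <- lapply(keep, function(id) {
    m <- ordinal_payoffs(games[[id]])
    attr(m, "family") <- fams[[id]]
    attr(m, "canonical_id") <- id
    m
  })
  stats::setNames(out, keep)
}
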