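# shared fixtures and independent brute-force oracles

pd_game <- function(...) canonical_game("prisoners_dilemma", ...)
bos_game <- function(...) canonical_game("battle_of_the_sexes", ...)

# strict coordination game with opposed preferred equilibria (BoS pattern)
bos_pattern <- function() {
  ordinal_game(ranks_p1 = matrix(c(4, 2, 1, 3), 2, 2, byrow = TRUE),
               ranks_p2 = matrix(c(3, 1, 2, 4), 2, 2, byrow = TRUE))
}

# game without any pure equilibrium (matching-pennies-like cycle)
cyclic_example <- function() {
  ordinal_game(ranks_p1 = matrix(c(4, 1, 2, 3), 2, 2, byrow = TRUE),
               ranks_p2 = matrix(c(1, 3, 4, 2), 2, 2, byrow = TRUE))
}

# enumerate all 576 strict rank assignments as raw (unreduced) games;
# written independently of the package's enumeration path
raw_strict_games <- function() {
  perms <- list()
  for (a in 1:4) for (b in 1:4) for (cc in 1:4) for (d in 1:4) {
    v <- c(a, b, cc, d)
    if (length(unique(v)) == 4L) perms[[length(perms) + 1L]] <- v
  }
  out <- list()
  for (p1 in perms) for (p2 in perms) {
    out[[length(out) + 1L]] <- list(r1 = matrix(p1, 2, 2, byrow = TRUE),
                                    r2 = matrix(p2, 2, 2, byrow = TRUE))
  }
  out
}

# oracle symmetry orbit of a raw game: the 4 images under row/column swaps,
# encoded as strings (independent re-implementation of the group action)
oracle_orbit <- function(g) {
  imgs <- character(0)
  for (sr in 0:1) for (sc in 0:1) {
    r1 <- g$r1; r2 <- g$r2
    if (sr) { r1 <- r1[c(2, 1), ]; r2 <- r2[c(2, 1), ] }
    if (sc) { r1 <- r1[, c(2, 1)]; r2 <- r2[, c(2, 1)] }
    imgs <- c(imgs, paste(c(t(r1), t(r2)), collapse = ""))
  }
  imgs
}

# oracle Nash check by exhaustive deviation testing on rank grids
oracle_nash <- function(r1, r2) {
  cells <- list()
  for (i in 1:2) for (j in 1:2) {
    better1 <- r1[3 - i, j] > r1[i, j]
    better2 <- r2[i, 3 - j] > r2[i, j]
    if (!better1 && !better2) cells[[length(cells) + 1L]] <- c(i, j)
  }
  cells
}

# random strict payoff matrix (distinct pay-offs per player) for properties
random_strict_matrix <- function(seed) {
  set.seed(seed)
  payoff_matrix(list(p1 = matrix(sample(0:20, 4), 2, 2),
                     p2 = matrix(sample(0:20, 4), 2, 2)),
                options_p1 = c("F", "J"),
                action_roles = list(cooperate = 1L, defect = 2L))
}

# transpose seats: the game as seen with players 1 and 2 interchanged
swap_seats <- function(m) {
  payoff_matrix(list(p1 = t(m$p2), p2 = t(m$p1)),
                options_p1 = m$options_p2, options_p2 = m$options_p1,
                action_roles = m$action_roles)
}

# raise a transport failure the way a live backend adapter would
transport_error <- function(msg) {
  stop(structure(class = c("games2x2_transport_error", "games2x2_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

# the topology is enumerated once per test run; several files consult it
TOPOLOGY <- enumerate_games()
TOPOLOGY_FAMILIES <- vapply(TOPOLOGY, classify_family, character(1))

# framing variants used by the relabelling/equivalence properties
variant_grid <- function() {
  list(
    neutral = make_variant(),
    random_swapped = make_variant(list(option_labels = "random",
                                       label_order = "swapped"), seed = 7),
    coins = make_variant(list(utility = "coins", explicit_end_goal = TRUE)),
    story = make_variant(list(cover_story = "cooking_competition",
                              utility = "dollars",
                              fallibility_notice = TRUE))
  )
}

# label_map for cooperate/defect personas under a given variant (tokens are
# positional: variant token i stands for declared option i)
persona_label_map <- function(matrix, variant) {
  toks <- variant$option_labels
  c(cooperate = toks[matrix$action_roles$cooperate],
    defect = toks[matrix$action_roles$defect])
}
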