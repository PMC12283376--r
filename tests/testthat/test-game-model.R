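test_that("payoff_matrix validates shape and labels and serves cell lookups", {
  pd <- canonical_game("prisoners_dilemma", neutral_labels = FALSE)
  expect_equal(payoff_at(pd, "Defect", "Cooperate"), c(10, 0))
  expect_equal(payoff_at(pd, "Cooperate", "Defect"), c(0, 10))
  bos <- canonical_game("battle_of_the_sexes", neutral_labels = FALSE)
  expect_equal(payoff_at(bos, "Football", "Football"), c(10, 7))

  expect_error(payoff_matrix(list(c(1, 1), c(2, 2), c(3, 3))),
               class = "games2x2_validation_error")
  expect_error(payoff_matrix(list(c(1, 1), c(2, 2), c(3, 3), c(4, 4)),
                             options_p1 = c("F", "F")),
               class = "games2x2_validation_error")
  expect_error(payoff_matrix(list(c(1, 1), c(2, 2), c(3, 3), c(Inf, 4))),
               class = "games2x2_validation_error")
  expect_error(canonical_game("chicken"), class = "games2x2_lookup_error")
})

test_that("canonical games print the published cells under neutral labels", {
  pd <- pd_game()
  expect_equal(pd$options_p1, c("F", "J"))
  expect_equal(as.numeric(pd$p1), c(8, 10, 0, 5))  # column-major
  expect_equal(as.numeric(pd$p2), c(8, 0, 10, 5))
  bos <- bos_game()
  expect_equal(payoff_at(bos, "F", "F"), c(10, 7))
  expect_equal(payoff_at(bos, "J", "J"), c(7, 10))
  expect_equal(payoff_at(bos, "F", "J"), c(0, 0))
})

test_that("to_ordinal ranks pay-offs ascending and rejects ties", {
  og <- to_ordinal(pd_game())
  # CC = 3rd best, CD = worst, DC = best, DD = 2nd (sort 8, 0, 10, 5)
  expect_equal(og$ranks_p1, matrix(c(3, 1, 4, 2), 2, 2, byrow = TRUE))
  expect_equal(og$ranks_p2, matrix(c(3, 4, 1, 2), 2, 2, byrow = TRUE))

  expect_error(to_ordinal(bos_game()), class = "games2x2_not_strict_error")

  ident <- payoff_matrix(list(c(1, 1), c(2, 3), c(3, 2), c(4, 4)))
  expect_equal(to_ordinal(ident)$ranks_p1, matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
})

test_that("enumeration quotients 576 raw strict games into 144 classes of orbit size 4", {
  raw <- raw_strict_games()
  expect_length(raw, 576)
  expect_length(TOPOLOGY, 144)

  # oracle: group raw games by their own-computed orbit; every orbit has
  # exactly 4 members (no strict game is fixed by a non-identity symmetry)
  orbit_keys <- vapply(raw, function(g) min(oracle_orbit(g)), character(1))
  expect_length(unique(orbit_keys), 144)
  expect_true(all(table(orbit_keys) == 4))

  # canonicalization is idempotent and lands inside the enumerated set
  for (id in sample(names(TOPOLOGY), 20)) {
    g <- TOPOLOGY[[id]]
    again <- canonicalize(canonicalize(g))
    expect_identical(ordinal_id(again), id)
  }
})

test_that("pure Nash equilibria match exhaustive deviation checks", {
  og_pd <- to_ordinal(pd_game())
  expect_equal(pure_nash(og_pd), list(c(2L, 2L)))  # (Defect, Defect) only
  expect_length(pure_nash(cyclic_example()), 0)

  for (g in TOPOLOGY) {
    expect_equal(pure_nash(g), oracle_nash(g$ranks_p1, g$ranks_p2))
  }

  # a (4,4) cell is always an equilibrium; no equilibrium holds a player at rank 1
  for (g in TOPOLOGY) {
    ns <- pure_nash(g)
    best <- which(g$ranks_p1 == 4 & g$ranks_p2 == 4)
    if (length(best)) {
      cell <- c((best - 1) %% 2 + 1, (best - 1) %/% 2 + 1)
      expect_true(any(vapply(ns, identical, logical(1), as.integer(cell))))
    }
    for (cc in ns) {
      expect_gt(g$ranks_p1[cc[1], cc[2]], 1)
      expect_gt(g$ranks_p2[cc[1], cc[2]], 1)
    }
  }
})

test_that("dominant strategies are detected per player", {
  og_pd <- to_ordinal(pd_game())
  expect_equal(dominant_strategy(og_pd, 1), 2L)  # Defect
  expect_equal(dominant_strategy(og_pd, 2), 2L)
  expect_true(is.na(dominant_strategy(bos_pattern(), 1)))
  expect_true(is.na(dominant_strategy(bos_pattern(), 2)))

  g <- ordinal_game(matrix(c(4, 3, 2, 1), 2, 2, byrow = TRUE),
                    matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(dominant_strategy(g, 1), 1L)
})

test_that("family classification is a partition with the published sizes", {
  expect_equal(classify_family(to_ordinal(pd_game())), "pd_family")
  expect_equal(classify_family(bos_pattern()), "biased")
  expect_equal(classify_family(cyclic_example()), "cyclic")

  expect_true(all(TOPOLOGY_FAMILIES %in% c(game_families(), "unclassified")))
  sizes <- table(TOPOLOGY_FAMILIES)
  expect_equal(as.integer(sizes[c("win_win", "pd_family", "unfair", "cyclic",
                                  "biased", "second_best", "unclassified")]),
               c(36L, 7L, 19L, 18L, 44L, 12L, 8L))
})

test_that("max_ideal_score multiplies the best cell by the round count", {
  expect_equal(max_ideal_score(pd_game(), 1, 10), 100)
  expect_equal(max_ideal_score(bos_game(), 2, 10), 100)
  m <- random_strict_matrix(3)
  expect_equal(max_ideal_score(m, 1, 1), max(m$p1))
  expect_error(max_ideal_score(pd_game(), 1, 0), class = "games2x2_validation_error")
})

test_that("family_table and game files round-trip through disk formats", {
  ft <- family_table(TOPOLOGY)
  expect_equal(nrow(ft), 144)
  expect_equal(anyDuplicated(ft$canonical_id), 0)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(ft, csv, row.names = FALSE)
  expect_equal(utils::read.csv(csv, stringsAsFactors = FALSE)$family, ft$family)

  gfile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(options_p1 = c("F", "J"), options_p2 = c("F", "J"),
                        cells = list(c(8, 8), c(0, 10), c(10, 0), c(5, 5)),
                        action_roles = list(cooperate = 1, defect = 2)), gfile)
  g <- read_game(gfile)
  expect_equal(payoff_at(g, "J", "F"), c(10, 0))
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(options_p1 = c("F", "J")), bad)
  expect_error(read_game(bad), class = "games2x2_validation_error")
})
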