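test_that("variants validate their fields and default to neutral framing", {
  v <- make_variant()
  expect_equal(v$option_labels, c("F", "J"))
  expect_equal(v$utility, "points")
  expect_null(v$cover_story)

  expect_error(make_variant(list(utility = "shells")),
               class = "games2x2_validation_error")
  expect_error(make_variant(list(cover_story = "space_opera")),
               class = "games2x2_validation_error")
  expect_error(make_variant(list(option_labels = c("FF", "J"))),
               class = "games2x2_validation_error")
  expect_error(make_variant(list(option_labels = "random")),
               class = "games2x2_validation_error")  # seed required
})

test_that("random label draws are deterministic in the seed and leave the RNG alone", {
  a <- make_variant(list(option_labels = "random"), seed = 11)
  b <- make_variant(list(option_labels = "random"), seed = 11)
  expect_identical(a$option_labels, b$option_labels)
  expect_length(unique(a$option_labels), 2)

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_variant(list(option_labels = "random"), seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("rendered rules state every cell's pay-offs and respect the variant", {
  bos <- bos_game()
  rules <- render_rules(bos)
  expect_match(rules, "If you choose Option F and the other player chooses Option F, then you win 10 points and the other player wins 7 points.", fixed = TRUE)
  expect_match(rules, "If you choose Option J and the other player chooses Option J, then you win 7 points and the other player wins 10 points.", fixed = TRUE)

  coins <- render_rules(bos, make_variant(list(utility = "coins")))
  expect_identical(gsub("coins", "points", coins), rules)

  # swapping presentation order reorders clauses but never changes numbers
  swapped <- render_rules(bos, make_variant(list(label_order = "swapped")))
  first_clause <- grep("^If", strsplit(swapped, "\n")[[1]], value = TRUE)[1]
  expect_match(first_clause, "Option J and the other player chooses Option J")
  nums <- function(s) sort(as.numeric(unlist(regmatches(s, gregexpr("[0-9]+", s)))))
  expect_equal(nums(swapped), nums(rules))

  # rendering is pure: byte-identical on repeated calls
  expect_identical(render_rules(bos, variant_grid()$story),
                   render_rules(bos, variant_grid()$story))
})

test_that("seat-2 rules describe the game from player 2's perspective", {
  bos <- bos_game()
  r2 <- render_rules(bos, role = 2)
  expect_match(r2, "If you choose Option F and the other player chooses Option F, then you win 7 points and the other player wins 10 points.", fixed = TRUE)
})

test_that("history lines mirror the seat's perspective round for round", {
  pd <- pd_game()
  tr <- play_match(pd, scripted_agent("always_defect"),
                   scripted_agent("always_cooperate"),
                   match_config(n_rounds = 1))
  h1 <- render_history(tr, 1)
  expect_match(h1, "In round 1, you chose Option J and the other player chose Option F. You won 10 points and the other player won 0 points.", fixed = TRUE)
  h2 <- render_history(tr, 2)
  expect_match(h2, "you chose Option F and the other player chose Option J. You won 0 points and the other player won 10 points.", fixed = TRUE)

  empty <- play_match(pd, scripted_agent("always_cooperate"),
                      scripted_agent("always_cooperate"),
                      match_config(n_rounds = 1))
  empty$rounds <- list()
  expect_equal(render_history(empty, 1), "This is the first round.")
  expect_error(render_history(tr, 3), class = "games2x2_validation_error")
})

test_that("prompts concatenate rules, history and query with matching option tokens", {
  bos <- bos_game()
  empty <- play_match(bos, scripted_agent("stubborn_preferred"),
                      scripted_agent("alternator"), match_config(n_rounds = 1))
  empty$rounds <- list()
  p <- build_prompt(bos, empty, 1, query_kind = "choose")
  expect_match(p$text, "This is the first round.", fixed = TRUE)
  expect_match(p$text, "round 1. Q: Which option do you choose")
  expect_true(all(vapply(p$option_tokens, grepl, logical(1), x = p$text, fixed = TRUE)))

  tr4 <- play_match(bos, scripted_agent("always_option", option = "F"),
                    scripted_agent("alternator"), match_config(n_rounds = 4))
  pp <- build_prompt(bos, tr4, 1, query_kind = "predict_opponent")
  expect_match(pp$text, "do you predict the other player")
  hist_lines <- grep("^In round", strsplit(pp$text, "\n")[[1]], value = TRUE)
  expect_length(hist_lines, 4)
  expect_match(hist_lines[1], "other player chose Option F")
  expect_match(hist_lines[2], "other player chose Option J")

  po <- build_prompt(bos, tr4, 1, query_kind = "observe_predict")
  expect_false(grepl("\\byou\\b|\\bYou\\b", render_rules(bos, perspective = "observer")))
  expect_match(po$text, "Which option will player 2 choose")
  expect_error(build_prompt(bos, empty, 1, query_kind = "observe_predict"),
               class = "games2x2_validation_error")
})

test_that("interventions and stories add framing text without touching pay-offs", {
  pd <- pd_game()
  v <- make_variant(list(cover_story = "collaborative_project",
                         fallibility_notice = TRUE,
                         opponent_info = "The other player will defect once but otherwise cooperate.",
                         explicit_end_goal = TRUE))
  rules <- render_rules(pd, v)
  expect_match(rules, "collaborative project")
  expect_match(rules, "sometimes makes mistakes")
  expect_match(rules, "defect once but otherwise cooperate", fixed = TRUE)
  expect_match(rules, "as many points as possible")
  plain <- render_rules(pd)
  nums <- function(s) sort(as.numeric(unlist(regmatches(s, gregexpr("[0-9]+", s)))))
  # same pay-off numbers (framing adds no numeric content beyond the horizon)
  expect_equal(setdiff(nums(rules), nums(plain)), numeric(0))
})
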