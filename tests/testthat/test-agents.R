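actions_of <- function(tr, role) transcript_rounds(tr)[[paste0("action_p", role)]]

test_that("scripted strategies play their defining sequences", {
  pd <- pd_game()
  bos <- bos_game()

  # false defector: defect once, cooperate ever after (C = F, D = J)
  tr <- play_match(pd, scripted_agent("false_defector"),
                   scripted_agent("always_cooperate"))
  expect_equal(actions_of(tr, 1), c("J", rep("F", 9)))

  # alternator seated second starts on the opponent's preferred option
  tr <- play_match(bos, scripted_agent("always_option", option = "F"),
                   scripted_agent("alternator"))
  expect_equal(actions_of(tr, 2), rep(c("F", "J"), 5))
  # and seated first, starts on player 2's preferred option (J)
  tr <- play_match(bos, scripted_agent("alternator"),
                   scripted_agent("always_option", option = "F"))
  expect_equal(actions_of(tr, 1), rep(c("J", "F"), 5))

  # grim trigger never fires against a constant cooperator...
  tr <- play_match(pd, scripted_agent("grim_trigger"),
                   scripted_agent("always_cooperate"))
  expect_equal(actions_of(tr, 1), rep("F", 10))
  # ...and fires permanently after one defection
  tr <- play_match(pd, scripted_agent("grim_trigger"),
                   scripted_agent("false_defector"))
  expect_equal(actions_of(tr, 1), c("F", rep("J", 9)))

  tr <- play_match(bos, scripted_agent("stubborn_preferred"),
                   scripted_agent("alternator"))
  expect_equal(actions_of(tr, 1), rep("F", 10))

  expect_error(scripted_agent("tit_for_tat"))
  expect_error(scripted_agent("always_option"), class = "games2x2_validation_error")
  # cooperate/defect strategies need the role metadata
  expect_error(play_match(bos, scripted_agent("always_cooperate"),
                          scripted_agent("alternator")),
               class = "games2x2_validation_error")
})

test_that("parse_choice takes the restricted argmax and flags the degenerate cases", {
  expect_equal(parse_choice(c(F = 0.6, J = 0.3, The = 0.1), c("F", "J")), "F")
  expect_equal(parse_choice(c(Other = 0.9, J = 0.1), c("F", "J")), "J")
  expect_error(parse_choice(c(A = 1.0), c("F", "J")),
               class = "games2x2_unparseable_error")
  expect_warning(tie <- parse_choice(c(F = 0.5, J = 0.5), c("F", "J")), "tie")
  expect_equal(tie, "F")

  # invariance to mass on non-option tokens
  set.seed(42)
  for (k in 1:25) {
    base <- c(F = runif(1), J = runif(1))
    if (base["F"] == base["J"]) next
    junk <- stats::setNames(runif(3), c("The", "Option", "A"))
    expect_equal(parse_choice(c(base, junk), c("F", "J")),
                 parse_choice(base, c("F", "J")))
  }
})

test_that("mock personas through the full prompt loop equal their scripted twins", {
  pd <- pd_game()
  pairs <- list(
    list(persona = "grim", scripted = "grim_trigger"),
    list(persona = "cooperative", scripted = "always_cooperate")
  )
  opponents <- list(scripted_agent("false_defector"),
                    scripted_agent("always_defect"),
                    scripted_agent("alternator"))
  for (v in variant_grid()) {
    lm <- persona_label_map(pd, v)
    for (pr in pairs) {
      mock <- text_agent(mock_backend(pr$persona, label_map = lm), "mock")
      twin <- scripted_agent(pr$scripted)
      for (opp in opponents) {
        for (seat in 1:2) {
          args_m <- if (seat == 1) list(pd, mock, opp) else list(pd, opp, mock)
          args_s <- if (seat == 1) list(pd, twin, opp) else list(pd, opp, twin)
          tr_m <- do.call(play_match, c(args_m, list(variant1 = v, variant2 = v)))
          tr_s <- do.call(play_match, c(args_s, list(variant1 = v, variant2 = v)))
          expect_equal(actions_of(tr_m, seat), actions_of(tr_s, seat))
          expect_equal(actions_of(tr_m, 3 - seat), actions_of(tr_s, 3 - seat))
        }
      }
    }
  }
})

test_that("the stubborn persona recovers its preferred option from the rules text", {
  bos <- bos_game()
  for (v in variant_grid()) {
    mock <- text_agent(mock_backend("stubborn"), "mock_stubborn")
    twin <- scripted_agent("stubborn_preferred")
    for (seat in 1:2) {
      args_m <- if (seat == 1) list(bos, mock, scripted_agent("alternator"))
                else list(bos, scripted_agent("alternator"), mock)
      args_s <- if (seat == 1) list(bos, twin, scripted_agent("alternator"))
                else list(bos, scripted_agent("alternator"), twin)
      tr_m <- do.call(play_match, c(args_m, list(variant1 = v, variant2 = v)))
      tr_s <- do.call(play_match, c(args_s, list(variant1 = v, variant2 = v)))
      expect_identical(transcript_rounds(tr_m), transcript_rounds(tr_s))
    }
  }
})

test_that("scripted_replay ignores history and replays its move list", {
  bos <- bos_game()
  mock <- text_agent(mock_backend("scripted_replay", moves = c("F", "J")), "replay")
  tr <- play_match(bos, mock, scripted_agent("always_option", option = "F"),
                   match_config(n_rounds = 4))
  expect_equal(actions_of(tr, 1), c("F", "J", "F", "J"))
})

test_that("social chain-of-thought records predictions and best-responds to them", {
  bos <- bos_game()
  sa <- scot_agent(mock_backend("alternation_predictor"), "scot_mock")
  tr <- play_match(bos, sa, scripted_agent("alternator"))
  preds <- transcript_predictions(tr, 1)
  expect_equal(nrow(preds), 10)
  # the alternating pattern is extrapolated correctly from round 3 onward
  expect_true(all((preds$predicted == preds$actual)[3:10]))
  # once the prediction is right, the action is the best response to it:
  # coordination on the alternating equilibrium
  acts <- transcript_rounds(tr)
  expect_equal(acts$action_p1[3:10], acts$action_p2[3:10])

  # deterministic: identical run on replay
  tr2 <- play_match(bos, sa, scripted_agent("alternator"))
  expect_identical(transcript_rounds(tr), transcript_rounds(tr2))
  expect_identical(transcript_predictions(tr2, 1), preds)
})

test_that("an unparseable prediction aborts before any action is emitted", {
  bos <- bos_game()
  backend <- text_backend(function(text) {
    if (grepl("do you predict", text)) c(Gibberish = 1) else c(F = 1)
  }, description = "broken_predictor")
  expect_error(
    scot_decide(backend, bos, 1,
                play_match(bos, scripted_agent("alternator"),
                           scripted_agent("alternator"),
                           match_config(n_rounds = 1))),
    class = "games2x2_unparseable_error")
})

test_that("observer mode extrapolates an external game's pattern", {
  bos <- bos_game()
  tr <- play_match(bos, scripted_agent("stubborn_preferred"),
                   scripted_agent("alternator"), match_config(n_rounds = 4))
  mock <- mock_backend("alternation_predictor")
  p2 <- observer_predict(mock, bos, tr, target_player = 2)
  expect_equal(p2$predicted, "F")  # history F J F J -> alternation continues
  p1 <- observer_predict(mock, bos, tr, target_player = 1)
  expect_equal(p1$predicted, "F")  # constant play extrapolates to itself

  empty <- tr; empty$rounds <- list()
  expect_error(observer_predict(mock, bos, empty),
               class = "games2x2_validation_error")
})

test_that("the mock backend treats an unparsable prompt as a contract breach", {
  mock <- mock_backend("grim", label_map = c(cooperate = "F", defect = "J"))
  expect_error(mock$complete("gibberish without a query"),
               class = "games2x2_contract_error")
  # a choose query with no history section at all is a prompting regression
  broken <- "Q: Which option do you choose, Option F or Option J? A: Option"
  expect_error(mock$complete(broken), class = "games2x2_contract_error")
})

test_that("transport errors are retried, unparseable answers are not", {
  calls <- 0L
  flaky <- text_backend(function(text) {
    calls <<- calls + 1L
    if (calls < 3L) transport_error("connection reset")
    c(F = 1)
  }, description = "flaky")
  pd <- pd_game()
  tr0 <- play_match(pd, scripted_agent("always_cooperate"),
                    scripted_agent("always_cooperate"),
                    match_config(n_rounds = 1))
  tr0$rounds <- list()
  res <- text_agent_decide(flaky, pd, 1, tr0)
  expect_equal(res$action, "F")
  expect_equal(calls, 3L)

  dead <- text_backend(function(text) transport_error("down"), description = "dead")
  expect_error(text_agent_decide(dead, pd, 1, tr0),
               class = "games2x2_transport_error")
})
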