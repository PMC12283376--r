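# games2x2

Simulation and benchmarking harness for **finitely repeated 2x2 games**
between pluggable agents: scripted human-like strategies and
text-completion-backed policies. The package is built for behavioural
game theory applied to machine agents — seat a language-model-style
backend in a game by rendering the rules and history as text, read its
next token as a move, and measure how it cooperates and coordinates over
repeated rounds.

It provides:

* **Game model** — 2x2 pay-off matrices with validated cell lookup; the
  canonical Prisoner's Dilemma `(8,8) (0,10) / (10,0) (5,5)` and Battle
  of the Sexes `(10,7) (0,0) / (0,0) (7,10)`; pure Nash equilibria and
  dominant strategies; enumeration of the **144 canonical strict ordinal
  2x2 games** (the 576 rank assignments quotiented by within-player
  option swaps) and their classification into six structural families
  (win–win, PD family, unfair, cyclic, biased, second-best).
* **Prompting** — deterministic textual rendering of rules, per-round
  history and queries, with framing variants (random option letters,
  option order, points/dollars/coins, cover stories, fallibility notice,
  explicit opponent information) that never change the pay-offs.
* **Agents** — scripted strategies (always-cooperate/defect, false
  defector, grim trigger, alternator, stubborn-preferred); text agents
  with the argmax-over-option-tokens choice rule; a **social
  chain-of-thought** wrapper that first elicits a prediction of the
  opponent's move; observer-mode prediction; and a deterministic mock
  backend whose personas answer by parsing the rendered prompt, so the
  whole loop is testable offline.
* **Engine** — simultaneous-move repeated matches with frozen pre-round
  histories, discounted utility \(U_i = \sum_t \delta^t \pi_i(x_{1t},
  x_{2t})\) (default: 10 rounds, \(\delta = 1\)), JSONL transcript
  archives.
* **Metrics & statistics** — coordination and joint-cooperation rates,
  defection and preferred-option rates, sustained-correct-prediction
  onset; paired and Welch two-sided t-tests with Cohen's d and
  noncentral-t confidence intervals, and the default **JZS Bayes
  factor** (Cauchy prior scale \(\sqrt{2}/2\)).
* **Tournament** — all-ordered-pairs schedules (including self-play),
  normalized scores (achieved / ideal total), per-family play counts and
  family-by-agent score tables.

## Worked example

```r
library(games2x2)

pd <- canonical_game("prisoners_dilemma")
tr <- play_match(pd, scripted_agent("grim_trigger"),
                 scripted_agent("false_defector"))
transcript_totals(tr)
#> [1] 90 10
joint_cooperation_rate(tr)
#> [1] 0
```

The false defector betrays once and then tries to cooperate; the grim
trigger never forgives, so from round 2 on every round is
(defect, cooperate) — 90 points for the unforgiving player, 10 for the
would-be cooperator, and not a single mutually cooperative round.

```r
bos <- canonical_game("battle_of_the_sexes")
tb <- play_match(bos, scripted_agent("stubborn_preferred"),
                 scripted_agent("alternator"))
coordination_rate(tb)
#> [1] 0.5
transcript_totals(tb)
#> [1] 50 35
```

A stubborn player that always picks its own preferred option meets a
turn-taking partner only on alternate rounds: coordination rate 0.5,
and both players leave most of the available pay-off on the table
(normalized scores 0.50 and 0.35).

```r
jzs_bayes_factor(3.34, 288)
#> [1] 14.89605
```

The same mock-backed loop works end to end:

```r
b <- mock_backend("grim", label_map = c(cooperate = "F", defect = "J"))
tr2 <- play_match(pd, text_agent(b, "mock_grim"),
                  scripted_agent("false_defector"))
transcript_totals(tr2)
#> [1] 90 10
```

See `vignettes/repeated-games.Rmd` for the full methods account and
`inst/cli/games2x2.R` for the command-line surface
(`enumerate`, `play`, `tournament`, `report`).

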