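---
title: "Benchmarking agents in finitely repeated 2x2 games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking agents in finitely repeated 2x2 games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(games2x2)
```

## Why repeated 2x2 games

Behavioural game theory studies how agents cooperate and coordinate by
observing their play in small, tightly controlled games. The same toolkit
transfers to machine agents: a text-completion model can be seated in a
game by describing the rules and history as text and reading its next
token as a move. `games2x2` is a simulation harness for this experimental
design. It covers two-player games with two discrete options each,
repeated a finite, disclosed number of rounds with full information,
played between any mix of scripted human-like strategies and
text-backed policies.

The stage game is a 2x2 pay-off matrix \((\pi_1(x_1,x_2),
\pi_2(x_1,x_2))\). Over \(n\) repetitions a player's utility is the
discounted sum

\[ U_i \;=\; \sum_{t=0}^{n-1} \delta^{\,t}\, \pi_i(x_{1t}, x_{2t}), \]

with discount factor \(\delta \in [0,1]\). The defaults — ten rounds,
\(\delta = 1\) — are the conditions under which the benchmark's published
results were obtained; `discounted_utility()` exposes the general form,
and the engine's tests pin the two limits (\(\delta = 1\): plain total;
\(\delta = 0\): first round only).

Two canonical matrices ship with the package. The Prisoner's Dilemma,

\[\begin{array}{ccc} & C & D \\ C & (8,8) & (0,10) \\ D & (10,0) & (5,5)\end{array}\]

probes cooperation: defection is dominant for both players, yet mutual
defection is Pareto-dominated by mutual cooperation. The Battle of the
Sexes,

\[\begin{array}{ccc} & F & B \\ F & (10,7) & (0,0) \\ B & (0,0) & (7,10)\end{array}\]

probes coordination under conflicting interests: both pure equilibria
beat miscoordination, but each player prefers a different one. By default
both games are presented under the neutral option tokens `F` and `J`
(first and second declared option), so that loaded words such as
"defect" cannot prime a text agent.

## The topology of strict ordinal games

For the family-level analysis the cardinal pay-offs are abstracted to
each player's preference ranking 1–4 over the four cells. There are
\(4! \times 4! = 576\) strict rank assignments; identifying games that
differ only by relabelling one player's two options (an order-4 group —
swapping rows and/or columns of both rank grids) leaves **144 canonical
classes**. Player interchange is deliberately *not* identified: the
topology counts a game and its mirrored seating as distinct, which is
what makes per-seat analysis meaningful (quotienting by player swap
would collapse the count to 78).

`classify_family()` partitions the 144 classes by their pure-Nash
structure:

| family | defining structure | classes | plays (3 agents) |
|---|---|---|---|
| cyclic | no pure equilibrium | 18 | 162 |
| win–win | a (4,4) cell | 36 | 324 |
| biased | a Pareto-best equilibrium of shape {4,3} | 44 | 396 |
| unfair | best equilibria of shape {4,2} | 19 | 171 |
| second-best | best equilibrium (3,3) | 12 | 108 |
| PD family | low equilibrium ({2,2}/{2,3}) strictly Pareto-dominated | 7 | 63 |
| unclassified | low equilibrium, no strictly better cell | 8 | — |

The rules are applied in the order listed; "Pareto-best equilibria" are
the pure Nash cells not Pareto-dominated by another Nash cell (four
classes have both a {2,4} and a {3,4} equilibrium and fall to *biased*,
whose definition — coordination pays, preferred outcomes oppose — they
meet). The eight residual classes are near-pure-conflict games whose
equilibrium cannot be jointly improved; they are not dilemmas in the
Prisoner's-Dilemma sense and not unfair in the {4,2} sense, so they are
retained under `unclassified` and excluded from family totals rather
than forced into a family. With three agents playing all ordered pairs
(including self-play) over the 136 six-family games, the schedule has
\(136 \times 9 = 1{,}224\) plays, split as in the table — the
acceptance script recomputes exactly these counts.

A deliberate design choice: topology-wide tournaments play the ordinal
games with their **ranks (1–4) as cardinal pay-offs**
(`ordinal_payoffs()`). No published cardinal matrices exist for the 144
classes, and the normalized score only requires a per-player maximum, so
rank pay-offs are the minimal faithful choice. Strictness matters here:
matrices with within-player ties (the Battle of the Sexes has two 0
cells per player) are perfectly playable in the engine but raise a
`not_strict` error on `to_ordinal()`, because the topology is defined
for strict games only.

## The prompt protocol

A match against a text backend is prompt chaining: each round, every
seat receives *rules → history → query* as one string
(`build_prompt()`), answers with a single token, and the updated history
is folded into the next round's prompt. The backend contract
(`text_backend()`) is minimal — prompt text in, a named vector of
next-token probability masses out. The chosen option is the **argmax of
the distribution restricted to the two valid option tokens**
(`parse_choice()`); mass on any other token is ignored. An exact tie
breaks to the first declared token with a warning: play at temperature 0
must be a deterministic function of the prompt, so some total order is
required, and the first-declared rule is the least surprising one.
A distribution with no mass on either option token is an *unparseable
answer*; it aborts the match with a status flag and the partial
transcript rather than substituting a default move, so failed
live-backend rounds remain auditable. Transport failures, by contrast,
are retried up to three times — they are a property of the connection,
not of the model.

Framing is factored into `prompt_variant` objects covering the
robustness dimensions: option tokens (neutral `F`/`J`, or two random
letters drawn — reproducibly, from a fixed seed — from a pool of
moderate-frequency English letters), presentation order, utility units
(points/dollars/coins), cover stories, a fallibility notice, explicit
opponent information, an explicit end-goal sentence and the disclosed
horizon. Variants change framing only; a property test asserts that the
pay-off numbers in the rendered rules are identical across all variants.
The template wording itself is the package's own canonical phrasing, one
template per query kind, snapshot-tested: what carries the science is
the variant machinery, not any particular sentence. History lines state
both players' choices and per-round scores; running totals are optional
(`cumulative = TRUE`) and off by default.

Three query kinds exist: `choose` (the agent's own move),
`predict_opponent` (the playing agent forecasts the other's next move)
and `observe_predict` (the agent is framed as a mere observer of two
external players — the rules and history are rendered in the third
person, with no "you" in the text). The **social chain-of-thought**
wrapper (`scot_agent()`) chains two queries: first a prediction, then a
choose prompt augmented with the stated prediction, recording both.

## Agents

Scripted strategies implement the human-like benchmark opponents:
always-one-option, always-cooperate/defect, the *false defector*
(defects in round 1, cooperates thereafter — probing whether trust can
be rebuilt), *grim trigger* (cooperates until the first observed
defection, then defects forever), the *alternator* (turn-taking, the
convention human pairs often converge to in Battle-of-the-Sexes-like
games; for courtesy it starts on the option the opponent prefers) and
*stubborn-preferred* (always its own best option). A player's "preferred
option" is the one indexing that player's maximum pay-off cell.

The `mock_backend()` personas mirror behavioural signatures reported for
large text models — unforgiving grim-trigger-like play in the Prisoner's
Dilemma, stubborn preferred-option play in the Battle of the Sexes, and
a pattern-extrapolating predictor. They are personas, i.e. behavioural
stand-ins for protocol testing, not claims about any model's mechanism;
their value is that they answer by *parsing the rendered prompt text*
(rules, history, announced prediction), so an end-to-end match through a
mock validates every link of the render/parse loop. The central
equivalence property — for each persona, the text agent over the mock
reproduces, round for round and under every framing variant and both
seatings, the action sequence of the directly scripted twin — is what
licenses reading the scripted results as the protocol's ground truth.
What the mocks do **not** show: anything about how a real model responds
to framing. A live model may well be sensitive to cover stories or label
changes; the mocks are constructed to be invariant. Passing variant
tests therefore validates the harness, never the robustness of a model.
The pattern-extrapolating persona locks onto the alternator from round 3
(two observations suffice for it); a real model's pickup round is an
empirical quantity, measured with `first_sustained_correct_round()`.

## Scoring and statistics

A seat's tournament score is normalized by ideal conditions: the
achieved total divided by `rounds × (that player's maximum cell
pay-off)` — the score the player would reach if every round landed in
its best cell. Tournament reports pool both seatings and self-play per
agent, and per-family play counts are pure schedule combinatorics,
independent of outcomes.

Comparisons between agents use the t family: `paired_t()` (differences
paired by game-seating, `df = n - 1`, Cohen's
\(d = \bar{x}_\mathrm{diff}/s_\mathrm{diff}\)) and `welch_t()`
(unequal-variance statistic with Welch–Satterthwaite df; Cohen's d on
the pooled SD, with a CI that is exact under equal variances and
approximate otherwise). Confidence intervals for d invert the
noncentral t distribution. Zero-variance differences raise a
degenerate-input error rather than returning a 0/0 statistic. Each
result also carries the default Bayesian t-test evidence ratio: a
Jeffreys–Zellner–Siow prior with Cauchy scale \(\sqrt{2}/2\) on the
standardized effect, computed as the noncentral-t density averaged over
the Cauchy prior by adaptive quadrature at relative tolerance
\(10^{-6}\) (`jzs_bayes_factor()`). The test suite cross-checks this
against an independent implementation of the equivalent g-prior
integral, verifies \(BF_{10} \cdot BF_{01} = 1\), monotonicity in
\(|t|\), and that the reference comparison \(t(287) = 3.34\) with 288
pairs yields \(d = 0.20\) (CI 0.08–0.31) and \(BF_{10} \approx 14.9\).

```{r stats-example}
jzs_bayes_factor(3.34, 288)
```

## A worked pair of matches

```{r worked}
pd <- canonical_game("prisoners_dilemma")
tr <- play_match(pd, scripted_agent("grim_trigger"),
                 scripted_agent("false_defector"))
transcript_totals(tr)      # (90, 10): one betrayal, then permanent defection
joint_cooperation_rate(tr) # no round has both players cooperating

bos <- canonical_game("battle_of_the_sexes")
tb <- play_match(bos, scripted_agent("stubborn_preferred"),
                 scripted_agent("alternator"))
coordination_rate(tb)      # 0.5: they meet only on alternate rounds
normalized_score(tb, 1)    # 50 / 100
```

## Numerical and protocol choices

* **Simultaneity** — both seats decide against the same frozen pre-round
  transcript; a sequential implementation would leak the current-round
  move.
* **Determinism** — scripted strategies and mocks are pure functions of
  (round, history); all randomization (label draws, schedule seeds)
  flows from explicit seeds, and a full config-driven tournament run is
  byte-identical on repetition.
* **Tie handling** — pay-off ties block only the ordinal abstraction;
  argmax ties in token space break to the first declared token with a
  warning; preferred-option ties resolve to the first maximal cell.
* **Actions are recorded under the matrix's own labels**, whatever
  tokens the variant showed, which is what makes behaviour metrics
  provably invariant under relabelling.
* **Degenerate inputs** — empty pay-off lists, zero-variance samples,
  zero ideal scores and out-of-range \(\delta\) raise typed errors
  (`games2x2_*_error`) rather than propagating NaNs.

The test suite runs the complete topology (all 576 raw games for the
orbit and idempotence properties), ten-round matches for every worked
example, a 5,000-replicate null simulation for the Welch test and a
10,000-replicate one for the paired test's type-I error, and full
1,224-play schedules for the counting identities; these sizes make the
whole suite run in well under a minute while leaving every claim
computed, not assumed.

## Limitations

The harness plays exactly-2x2, finite, full-information games; mixed
equilibria, continuation-probability (indefinite) horizons and more than
two players are out of scope. Live API adapters satisfy the backend
contract but are intentionally excluded from the test suite; every
shipped result is computed from scripted strategies and mock personas.
Multi-token option labels are rejected at variant creation — the argmax
contract is defined over single next-token alternatives.
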