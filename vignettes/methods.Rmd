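---
title: "Methods: food-group scoring, mission selection, and the simulated intervention loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: food-group scoring, mission selection, and the simulated intervention loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrimission)
```

`nutrimission` is a behaviour-change engine that works on dietary *food
groups* rather than calories or nutrients. This vignette is the package's
account of its model: the questionnaire and profiling step, the
guideline-anchored scoring system, the rule-based mission selection, the
motivational notification cadence, and the synthetic-user simulator, together
with the design decisions behind each and their limitations.

## Dietary assessment and profiling

The entry point is a 20-item food-frequency questionnaire (FFQ). Each item
belongs to one of 13 scored food groups and reports an average consumption
frequency as a count per **day**, **week**, or **month**. All downstream
computation uses servings/week: daily counts multiply by 7 and monthly counts
by 12/52, the calendar-exact average (no conversion factor is canonical for
"a month"; 12/52 keeps a year of months equal to a year of weeks). Counts may
be fractional — "2–3 times a week" is encoded as 2.5 — because FFQ bands are
household measures, not integers.

`build_profile()` sums the normalized frequencies of the items within each
food group, giving the weekly-serving profile that everything else consumes.
A short FFQ variant (13 items, still covering every group) is the monthly
follow-up: `apply_short_ffq()` overwrites only the groups the short schema
covers and leaves preferences and mission history untouched, so a
short-then-original sequence restores the starting profile exactly.

The dietary-habits questionnaire contributes a coeliac flag and a vegetarian
type (`none`, `vegan`, `ovo_vegetarian`, `lacto_ovo_vegetarian`); an optional
`liked_groups` set captures marked food preferences and only affects ranking
tie-breaks.

## The scoring system

Each food group carries, as configuration (`inst/extdata/guidelines.yaml`):

* a **recommended weekly serving interval** drawn from a public-health
  food guide ("eat more fruit, vegetables, pulses and nuts; switch to water,
  wholegrains, virgin olive oil; eat less salt, sugar, red and processed
  meat, and ultra-processed food");
* a **maximum score** encoding priority: 10 for the six groups with the
  largest health impact (vegetables, water, sugary foods, red meat, processed
  meat, ultra-processed foods), 9 for fruits, 8 for the others;
* a **score table**: a piecewise-constant map from weekly servings to an
  integer score, 0 inside the recommended interval and rising monotonically
  with distance from it, reaching the maximum at the saturating extreme
  (e.g. more than seven weekly servings of processed meat, or zero servings
  of fruit).

Scores are integers by design — the published examples of such scoring
systems are integer-valued — so tables map serving intervals to scores rather
than applying a continuous formula. Intervals are right-open `[lo, hi)`,
which makes boundary behaviour unambiguous: a limit-group boundary belongs to
the worse band. Tables are data so nutrition experts can revise cutoffs;
`validate_guidelines()` enforces every structural constraint (totality over
`[0, Inf)`, zero-inside-recommendation, monotonicity on each side, the 10/9/8
maximum assignment, and the nuts serving bands described below).

Scores band into a three-level adherence status used directly as the
gamified mission level: with the default global bands, score > 5 is level 1
(*poor*), 3–5 is level 2 (*average*), below 3 is level 3 (*good*). Bands can
be overridden per group; none of the shipped entries do, since only the
level-1 cutoff (> 5) is fixed by the design.

### The nuts table and level promotion

The nuts group doubles as the worked reference for mission eligibility: users
at 0, 1 or 2 weekly servings must be in the beginner mission (level 1), users
above 3 weekly servings in the expert one (level 3), and the advanced mission
(level 2) requires the beginner mission to be completed first. The shipped
nuts table is therefore deliberately binary — score 8 below 3 servings/week,
0 at or above — so that the status bands reproduce those serving bands
exactly, and level 2 is reachable *only* through the completion promotion in
`mission_level_for()`: completing the mission at your current level promotes
you one level (never past 3). Other groups have graded tables, so their
intermediate level is also reachable directly from intake.

## Mission selection

The catalogue (`inst/extdata/missions.yaml`) holds 39 missions: 13 food
groups × 3 levels, each with a compliance target (default 3 button presses)
and a time limit (default 7 days — "a unique time limit such as one week");
both are per-mission configuration because no per-mission targets are
canonical. The 13 groups are an editorial mapping of the food guide onto
scorable groups: red and processed meats are scored separately, and
"seasonal and locally grown foods" is treated as advisory rather than scored,
which is what makes the count come out at 13.

`rank_candidates()` orders food groups by descending score (largest deviation
first), breaking ties by group priority (`max_score`), then liked groups,
then the configured group order; groups whose expert mission is completed
drop out. The top three become the proposal shown to the user
(`propose_missions()`). One mission is active at a time; switching abandons
the old instance. `evaluate_progress()` classifies an active mission as
*completed* (target reached), *stuck* (no compliance event for
`stuck_after_days`, default 3 — a design choice, there is no canonical
window), *expired* (time limit passed), or *ongoing*. Expired missions are
handled like stuck ones — a re-proposal rather than a failure — which matches
the coping-planning stance that users should be redirected, not penalised.
On completion the next proposal is the next level of the same group when one
exists, otherwise the top of a fresh ranking.

## The rule engine

Mission selection also runs declaratively on a forward-chaining
production system: a working memory of keyed facts, a rule base, and an
inference engine (`dispatch()`). Conditions are conjunctions of simple
comparisons (`=`, `≠`, `<`, `≤`, `>`, `≥`, `in`, `present`, `absent`) on fact
keys — deliberately restricted, enough for all the scoring knowledge while
keeping the matcher auditable; there is no general pattern unification, Rete
network, or backward chaining. Conflict resolution is salience first, then
most recently asserted matched fact, then definition order. A rule becomes
refractory after firing until one of its matched facts is re-asserted — the
standard production-system reading of quiescence; dispatch therefore
terminates when no rule can add anything new, with a 1000-firing cycle guard
for runaway rule bases.

`rules_from_guidelines()` compiles the guideline config into the rule base:
one scoring rule per score-table interval, three banding rules per group, and
one low-salience proposal rule that fires once per questionnaire event. The
final ranking is an effect primitive that reads the score facts from working
memory — expressing a full sort in the restricted condition language would
require aggregation it intentionally lacks — and the package tests that the
rule route and the procedural pipeline agree on randomized profiles.

## The motivational repository and cadence

The repository holds three recommendation types: *Did you know…?* tips (one
food group each), general healthy-eating advice, and mission-linked
recommendations delivered in a curated order (`order_index`). The shipped
composition is 10 mission-linked entries per mission (390 total), 3 tips per
group, and 80 general entries — 509 recommendations, satisfying the more-than
-500 composition constraint. The text is generated placeholder prose:
composition is normative, wording is meant to be authored by nutritionists.
Every entry carries dietary-suitability tags; `eligible_recommendations()`
keeps an entry when its tags include every restriction the user's preferences
imply (coeliac ⇒ `gluten_free`; vegan ⇒ `vegan`; ovo/lacto-ovo ⇒ their own
tag or `vegan`). The first entry of every pool suits all preferences, so no
mission can be left without content for any preference combination. The tag
vocabulary (`omnivore`, `vegan`, `ovo_vegetarian`, `lacto_ovo_vegetarian`,
`gluten_free`) is a stated choice; the underlying design names only
"vegan, gluten-free, …".

The cadence (`build_schedule()`): on day 0 a one-time tip about the mission's
food group; a mission-linked recommendation every two days — days 2, 4 and 6
of each 7-day block; one general recommendation per block on day 5, shifted a
day later on collision. At most one notification per day. The intended weekly
volume is 3–4 notifications: a literal "every second calendar day" cadence
would produce five in some weeks once the weekly general is added, so the
every-two-days rhythm restarts with each week, giving exactly 3 + 1 in every
steady-state week (the first week carries 5 including the one-time onboarding
tip). Within a mission's pool, recommendations follow ascending
`order_index`, ties permuted by seed; nothing repeats until the pool is
exhausted, after which the rotation restarts. All scheduling is deterministic
given the seed; changing the seed permutes within pools but never alters
cadence or the one-per-day guarantee. When a mission is stuck,
`coping_notice()` offers the current top proposals minus the stuck mission as
alternatives.

## The synthetic-user simulator

The simulator makes every stage testable without participants. Each
`SimulatedUser` has a latent true intake per food group, drawn log-normally
(`meanlog = log(median)`, `sdlog = 0.5`) around medians describing a typical
improvable diet — low fruit/vegetable/nuts/wholegrain intake, water below
target, frequent sugary, red-meat, processed and ultra-processed choices —
plus three behavioural parameters: `compliance_prob` (daily probability of
pressing the mission button; default 0.9, an engaged user), `responsiveness`
(default 0.5), and `report_noise_sd` (default 0.5 servings/week of Gaussian
reporting noise, clamped at zero).

`simulate_user()` runs the loop day by day: answer the full FFQ (day 0),
receive and start the top proposal, deliver scheduled notifications, log
compliance stochastically, evaluate progress daily (completion → level-up and
next mission; stuck → coping notice; expiry → switch to the top alternative),
and answer the short FFQ every 28 days ("one-month progression"). Behaviour
change itself uses the minimal plausible dynamics: on each compliant week the
latent intake of the worked group moves toward its guideline target by the
responsiveness fraction, `x ← x + r·(target − x)`, where the target is the
midpoint of the recommended interval, or one serving inside it when the
interval is unbounded. Non-worked groups are never touched (conservation).
All randomness flows from explicit seeds; no global RNG state leaks.

What the simulator does *not* emulate: dropout, recall and social-desirability
bias beyond symmetric noise, weekday/weekend structure, interactions between
food groups (substitution effects), or any psychometric realism in how
motivation responds to notifications. Passing simulation tests therefore
demonstrates that the *engine* behaves as designed under plausible inputs —
scores fall, levels rise, cadences hold — not that the intervention changes
real behaviour; that question belongs to a controlled trial, which is out of
scope here.

## Numerical and scale choices

* Score lookups use `findInterval` over the table breakpoints; tables are
  validated total over `[0, Inf)` so no servings value can fall through.
* Ranking ties are resolved deterministically (priority, liked, configured
  order) so the proposal is a pure function of the profile.
* Test and demonstration scales: property tests sweep a 0–40 servings/week
  grid at 0.25 resolution; the rule-vs-pipeline equivalence test uses 1000
  randomized profiles; scheduling properties run over a 52-week horizon; the
  cohort regression test uses 200 users over 56 days at compliance 0.9
  against 0, checking that the median adherence status of each user's
  first-proposed food group improves in the engaged cohort and not in the
  inert one. These sizes were chosen as the smallest that exercise every
  steady-state regime (multiple level-ups, two short-FFQ refreshes, pool
  exhaustion).
* The CLI (`inst/cli/nutrimission.R`) persists session state as JSON with
  ISO-8601 dates; `save_state()`/`load_state()` round-trip exactly, and
  `--today`/`--seed` flags make every command reproducible under test.

## Known limitations

* The shipped score tables interpolate between the fixed anchor constraints
  (the maxima, the zero-inside-recommendation rule, and the nuts bands);
  intermediate cutoffs are editorial and meant to be reviewed by dietitians.
* Only the nuts missions carry meaningful text; the other 36 are structural
  placeholders.
* The condition language cannot express aggregations (counts, sums over
  facts), which is why ranking is an effect primitive rather than a rule.
* Recommendation `time_slot` tags are carried but the scheduler does not yet
  place notifications within the day.
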