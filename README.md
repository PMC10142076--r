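# nutrimission

Most nutrition apps track calories and nutrients meal by meal — burdensome,
inaccurate, and risky for users prone to disordered eating. `nutrimission`
implements the alternative: a behaviour-change engine that works at the
**food-group** level. A short food-frequency questionnaire (FFQ) profiles the
user once; each food group is scored against dietary-guideline serving
ranges; the worst-adhering groups become gamified **missions** (three levels:
beginner, advanced, expert) proposed through a rule-based recommender; and a
scheduler delivers a steady trickle of motivational recommendations filtered
by dietary preference (coeliac, vegan, ovo- or lacto-ovo-vegetarian). The
design follows the Health Action Process Approach (HAPA): one mission at a
time (intention formation), levels (planning), stuck detection with
alternative missions (coping), a monthly short FFQ (action control), and
congratulation on level-up (feedback).

The package is aimed at digital-health researchers and engineers who need a
testable, configuration-driven backend for this kind of intervention: all
scoring tables, the 39-mission catalogue, and the rule base are data (YAML),
and a seeded synthetic-user simulator exercises the whole loop without real
participants.

## The scoring model

For food group *g* with weekly servings *s*, the deviation score is a
piecewise-constant, integer-valued function

```
score_g(s) = 0                      if s is inside the recommended interval
score_g(s) -> max_score_g           monotonically as s moves away from it
```

with `max_score_g = 10` for the six highest-impact groups (vegetables, water,
sugary foods, red meat, processed meat, ultra-processed foods), `9` for
fruits, and `8` for the rest. Scores band into a three-level adherence status
(default: score > 5 → level 1 *poor*; 3–5 → level 2 *average*; < 3 → level 3
*good*), which is also the mission level the user is placed at (completing a
level promotes by one). Food groups are ranked by descending score and the
top three missions are proposed.

## Worked example

```r
library(nutrimission)

gl    <- load_guidelines()          # 13 food groups, scoring tables
cat39 <- load_catalogue()           # 39 missions = 13 groups x 3 levels
repo  <- build_repository(cat39)    # 509 recommendations, 390 mission-linked

# a user who eats a lot of cold meats and little of everything else
sch  <- ffq_schema()                # the 20-item FFQ
resp <- tibble::tibble(
  item_id = sch$items$item_id,
  count   = ifelse(sch$items$item_id == "cold_meats", 8, 0.5),
  period  = "week"
)
prof  <- build_profile(resp, dietary_prefs(), sch, user_id = "u1")
board <- score_profile(prof, gl)
head(dplyr::arrange(board, dplyr::desc(score)), 3)
#> # A tibble: 3 x 5
#>   food_group_id  weekly_servings score max_score level
#>   <chr>                    <dbl> <int>     <int> <int>
#> 1 vegetables                 1      10        10     1
#> 2 water                      0.5    10        10     1
#> 3 processed_meat             8.5    10        10     1

propose_missions(rank_candidates(board, prof, cat39, gl), cat39)$mission_id
#> [1] "vegetables_l1"     "water_l1"          "processed_meat_l1"
```

Three food groups hit their maximum score of 10: vegetables and water are far
below their recommended ranges, and processed meat at more than seven weekly
servings is far above its own. The tie resolves by the configured group order,
so the vegetables beginner mission leads the proposals. Starting it schedules
the notification cadence — a *Did you know…?* tip on day 0, a mission-linked
recommendation every two days, one general recommendation per week (3–4
notifications in any steady-state week):

```r
inst <- start_mission(cat39[cat39$mission_id == "vegetables_l1", ], "u1",
                      on = "2026-01-05")
build_schedule(inst, dietary_prefs(), repo, horizon_days = 7, seed = 1)
#> # A tibble: 5 x 4
#>     day date       rec_id                reason
#>   <int> <date>     <chr>                 <chr>
#> 1     0 2026-01-05 rec_dyk_vegetables_01 mission_start_tip
#> 2     2 2026-01-07 rec_vegetables_l1_01  mission_cadence
#> 3     4 2026-01-09 rec_vegetables_l1_02  mission_cadence
#> 4     5 2026-01-10 rec_gen_045           weekly_general
#> 5     6 2026-01-11 rec_vegetables_l1_03  mission_cadence
```

The same selection runs declaratively through the forward-chaining rule
engine (`propose_via_rules()`), and `simulate_user()` /
`simulate_cohort()` run seeded synthetic users through the complete loop:
compliance button presses, level-ups, stuck detection, and monthly short-FFQ
profile refreshes. A command-line surface over the same functions lives at
`inst/cli/nutrimission.R` (`init`, `ffq`, `propose`, `start`, `log`, `tick`,
`report`, `simulate`, `validate`).

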