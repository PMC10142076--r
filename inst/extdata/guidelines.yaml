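# Guideline scoring configuration: one entry per mission food group.
#
# The 13 food groups are an editorial mapping of the "eat more / switch to /
# eat less" targets of the Catalan public-health guide onto scorable groups:
# red and processed meats are scored separately, and "seasonal and locally
# grown foods" is treated as advisory-only (not scored).
#
# score_table rows are right-open serving intervals [lo, hi) in servings/week
# mapped to an integer score; tables must be total over [0, Inf), score 0
# inside the recommended interval, and monotone non-decreasing with distance
# from it. Maximum score encodes group priority: 10 for the six groups with
# the strongest health impact, 9 for fruits, 8 for all others.
#
# level_bands may override the global status bands (score > 5 -> level 1,
# 3..5 -> level 2, < 3 -> level 3); none of the shipped entries do.
food_groups:
  - food_group_id: fruits
    label: "Fruit"
    direction: encourage
    recommended_weekly: {lo: 14, hi: .inf}   # 2+ servings/day
    max_score: 9
    score_table:
      - {lo: 0,  hi: 2,  score: 9}
      - {lo: 2,  hi: 4,  score: 8}
      - {lo: 4,  hi: 7,  score: 6}
      - {lo: 7,  hi: 10, score: 4}
      - {lo: 10, hi: 14, score: 2}
      - {lo: 14, hi: .inf, score: 0}
  - food_group_id: vegetables
    label: "Vegetables"
    direction: encourage
    recommended_weekly: {lo: 14, hi: .inf}   # 2+ servings/day
    max_score: 10
    score_table:
      - {lo: 0,  hi: 2,  score: 10}
      - {lo: 2,  hi: 4,  score: 9}
      - {lo: 4,  hi: 7,  score: 7}
      - {lo: 7,  hi: 10, score: 5}
      - {lo: 10, hi: 14, score: 3}
      - {lo: 14, hi: .inf, score: 0}
  - food_group_id: pulses
    label: "Pulses and legumes"
    direction: encourage
    recommended_weekly: {lo: 3, hi: .inf}    # 3-4 servings/week
    max_score: 8
    score_table:
      - {lo: 0, hi: 1, score: 8}
      - {lo: 1, hi: 2, score: 6}
      - {lo: 2, hi: 3, score: 4}
      - {lo: 3, hi: .inf, score: 0}
  - food_group_id: nuts
    label: "Nuts"
    direction: encourage
    recommended_weekly: {lo: 3, hi: .inf}    # 3-7 servings/week
    max_score: 8
    # Binary by design: 0/1/2 servings/week must band to level 1 (poor) and
    # anything beyond 3/week to level 3 (good); the intermediate level is
    # reached by completing the beginner mission, not by intake alone.
    score_table:
      - {lo: 0, hi: 3, score: 8}
      - {lo: 3, hi: .inf, score: 0}
  - food_group_id: water
    label: "Water"
    direction: encourage
    recommended_weekly: {lo: 28, hi: .inf}   # 4+ glasses/day as floor
    max_score: 10
    score_table:
      - {lo: 0,  hi: 7,  score: 10}
      - {lo: 7,  hi: 14, score: 8}
      - {lo: 14, hi: 21, score: 5}
      - {lo: 21, hi: 28, score: 3}
      - {lo: 28, hi: .inf, score: 0}
  - food_group_id: wholegrains
    label: "Wholegrain bread, pasta and rice"
    direction: encourage
    recommended_weekly: {lo: 7, hi: .inf}    # 1+ serving/day
    max_score: 8
    score_table:
      - {lo: 0, hi: 3, score: 8}
      - {lo: 3, hi: 5, score: 5}
      - {lo: 5, hi: 7, score: 3}
      - {lo: 7, hi: .inf, score: 0}
  - food_group_id: olive_oil
    label: "Virgin olive oil"
    direction: encourage
    recommended_weekly: {lo: 7, hi: .inf}    # 1+ use/day
    max_score: 8
    score_table:
      - {lo: 0, hi: 3, score: 8}
      - {lo: 3, hi: 5, score: 5}
      - {lo: 5, hi: 7, score: 3}
      - {lo: 7, hi: .inf, score: 0}
  - food_group_id: fish
    label: "Fish and seafood"
    direction: encourage
    recommended_weekly: {lo: 2, hi: 5}       # 2-4 servings/week
    max_score: 8
    score_table:
      - {lo: 0, hi: 1, score: 8}
      - {lo: 1, hi: 2, score: 4}
      - {lo: 2, hi: 5, score: 0}
      - {lo: 5, hi: .inf, score: 2}
  - food_group_id: salt
    label: "Salt and salty snacks"
    direction: limit
    recommended_weekly: {lo: 0, hi: 3}
    max_score: 8
    score_table:
      - {lo: 0, hi: 3, score: 0}
      - {lo: 3, hi: 5, score: 3}
      - {lo: 5, hi: 7, score: 5}
      - {lo: 7, hi: .inf, score: 8}
  - food_group_id: sugary_foods
    label: "Sugary foods and drinks"
    direction: limit
    recommended_weekly: {lo: 0, hi: 3}
    max_score: 10
    score_table:
      - {lo: 0, hi: 3, score: 0}
      - {lo: 3, hi: 5, score: 4}
      - {lo: 5, hi: 7, score: 7}
      - {lo: 7, hi: .inf, score: 10}
  - food_group_id: red_meat
    label: "Red meat"
    direction: limit
    recommended_weekly: {lo: 0, hi: 4}       # at most 3 servings/week
    max_score: 10
    score_table:
      - {lo: 0, hi: 4, score: 0}
      - {lo: 4, hi: 6, score: 4}
      - {lo: 6, hi: 7, score: 7}
      - {lo: 7, hi: .inf, score: 10}
  - food_group_id: processed_meat
    label: "Processed meat and cold cuts"
    direction: limit
    recommended_weekly: {lo: 0, hi: 3}
    max_score: 10
    # Maximum score beyond seven servings/week.
    score_table:
      - {lo: 0, hi: 3, score: 0}
      - {lo: 3, hi: 5, score: 4}
      - {lo: 5, hi: 7, score: 7}
      - {lo: 7, hi: .inf, score: 10}
  - food_group_id: ultraprocessed
    label: "Ultra-processed foods"
    direction: limit
    recommended_weekly: {lo: 0, hi: 3}
    max_score: 10
    score_table:
      - {lo: 0, hi: 3, score: 0}
      - {lo: 3, hi: 5, score: 4}
      - {lo: 5, hi: 7, score: 7}
      - {lo: 7, hi: .inf, score: 10}
level_bands:
  poor_above: 5      # score > 5          -> level 1 (poor)
  good_below: 3      # score < 3          -> level 3 (good); else level 2
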