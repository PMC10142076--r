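test_that("the default repository satisfies the composition constraints", {
  expect_gt(nrow(repo), 500L)
  expect_equal(sum(repo$rec_type == "mission_linked"), 390L)
  # 10 per mission over all 39 missions
  per_mission <- table(repo$mission_id[repo$rec_type == "mission_linked"])
  expect_length(per_mission, 39L)
  expect_true(all(per_mission == 10L))
  # every food group has at least one Did-you-know tip
  expect_setequal(
    unique(repo$food_group_id[repo$rec_type == "did_you_know"]),
    attr(cat39, "food_groups")
  )
  expect_equal(nrow(validate_repository(repo, cat39)), 0L)
})

test_that("the validator flags broken compositions with counts", {
  small <- repo[repo$rec_type != "general", ]
  v <- validate_repository(small, cat39)
  expect_true(any(v$check == "total"))

  no_nuts <- repo[!(repo$rec_type == "mission_linked" &
                      repo$mission_id == "nuts_l1"), ]
  v2 <- validate_repository(no_nuts, cat39)
  expect_true(any(grepl("nuts_l1", v2$message)))
  expect_true(any(v2$check == "mission_linked_count"))
})

test_that("repository JSON round-trips through load_repository", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    purrr::map(seq_len(nrow(repo)), function(i) {
      r <- as.list(repo[i, ])
      r$dietary_tags <- r$dietary_tags[[1]]
      r
    }),
    f, auto_unbox = TRUE, null = "null", na = "null"
  )
  re <- load_repository(f, cat39)
  expect_equal(nrow(re), nrow(repo))
  expect_equal(re$rec_id, repo$rec_id)
  expect_equal(re$dietary_tags, repo$dietary_tags)
})

test_that("dietary filtering equals the brute-force tag rule", {
  combos <- tidyr::expand_grid(
    coeliac = c(FALSE, TRUE),
    veg = c("none", "vegan", "ovo_vegetarian", "lacto_ovo_vegetarian")
  )
  for (i in seq_len(nrow(combos))) {
    prefs <- dietary_prefs(combos$coeliac[i], combos$veg[i])
    got <- eligible_recommendations(repo, prefs)
    keep <- vapply(repo$dietary_tags, function(tags) {
      ok <- !prefs$coeliac || "gluten_free" %in% tags
      ok && switch(prefs$vegetarian_type,
        none = TRUE,
        vegan = "vegan" %in% tags,
        ovo_vegetarian = any(c("ovo_vegetarian", "vegan") %in% tags),
        lacto_ovo_vegetarian = any(c("lacto_ovo_vegetarian", "vegan") %in% tags)
      )
    }, TRUE)
    expect_equal(got$rec_id, repo$rec_id[keep])
    # every mission keeps at least one eligible mission-linked entry
    ml <- got[got$rec_type == "mission_linked", ]
    expect_setequal(unique(ml$mission_id), cat39$mission_id)
  }
  # unrestricted users see everything
  expect_equal(nrow(eligible_recommendations(repo, dietary_prefs())), nrow(repo))
})

test_that("the schedule follows the tip / every-2-days / weekly cadence", {
  inst <- start_mission(cat39[cat39$mission_id == "nuts_l1", ], "u1",
                        on = "2026-01-05")
  # calendar oracle for the first week: tip day 0, mission days 2/4/6,
  # general day 5 -> 5 notifications
  s7 <- build_schedule(inst, dietary_prefs(), repo, horizon_days = 7, seed = 1)
  expect_equal(nrow(s7), 5L)
  expect_equal(s7$day, c(0L, 2L, 4L, 5L, 6L))
  expect_equal(s7$reason,
               c("mission_start_tip", "mission_cadence", "mission_cadence",
                 "weekly_general", "mission_cadence"))
  expect_true(s7$rec_id[1] %in%
                repo$rec_id[repo$rec_type == "did_you_know" &
                              repo$food_group_id == "nuts"])

  # steady state: the second week carries 4 notifications
  s14 <- build_schedule(inst, dietary_prefs(), repo, horizon_days = 14, seed = 1)
  wk2 <- s14[s14$day >= 7 & s14$day < 14, ]
  expect_equal(nrow(wk2), 4L)

  # horizon 1: only the onboarding tip
  s1 <- build_schedule(inst, dietary_prefs(), repo, horizon_days = 1, seed = 1)
  expect_equal(s1$reason, "mission_start_tip")
  expect_equal(s1$day, 0L)
})

test_that("long-horizon weeks always hold 3-4 notifications and one per day", {
  inst <- start_mission(cat39[cat39$mission_id == "fruits_l1", ], "u1",
                        on = "2026-01-05")
  s <- build_schedule(inst, dietary_prefs(), repo, horizon_days = 364, seed = 7)
  expect_false(any(duplicated(s$day)))
  weekly <- table(s$day %/% 7L)
  steady <- weekly[as.integer(names(weekly)) >= 1]
  expect_true(all(steady >= 3 & steady <= 4))
})

test_that("mission recommendations follow order_index then rotate without repeats", {
  inst <- start_mission(cat39[cat39$mission_id == "fruits_l1", ], "u1",
                        on = "2026-01-05")
  s <- build_schedule(inst, dietary_prefs(), repo, horizon_days = 364, seed = 7)
  ml <- s$rec_id[s$reason == "mission_cadence"]
  pool <- repo[repo$rec_type == "mission_linked" &
                 repo$mission_id == "fruits_l1", ]
  # first pass is the curated ascending order
  expect_equal(ml[1:10], pool$rec_id[order(pool$order_index)])
  # no repeats until the pool of 10 is exhausted, over the whole year
  chunks <- split(ml, (seq_along(ml) - 1L) %/% 10L)
  for (ch in chunks) expect_equal(anyDuplicated(ch), 0L)
})

test_that("scheduling is deterministic in the seed and seed changes keep cadence", {
  inst <- start_mission(cat39[cat39$mission_id == "nuts_l2", ], "u1",
                        on = "2026-01-05")
  a <- build_schedule(inst, dietary_prefs(), repo, horizon_days = 56, seed = 11)
  b <- build_schedule(inst, dietary_prefs(), repo, horizon_days = 56, seed = 11)
  expect_identical(a, b)
  c_ <- build_schedule(inst, dietary_prefs(), repo, horizon_days = 56, seed = 12)
  expect_equal(a$day, c_$day)
  expect_equal(a$reason, c_$reason)
})

test_that("coping notices require a stuck mission and list alternatives", {
  inst <- start_mission(cat39[cat39$mission_id == "nuts_l1", ], "u1",
                        on = "2026-01-05")
  expect_error(coping_notice(inst, cat39[1:2, ]), "stuck missions only")

  prof <- profile_with(c(nuts = 0, fruits = 0, sugary_foods = 10))
  ranked <- rank_candidates(score_profile(prof, gl), prof, cat39, gl)
  props <- propose_missions(ranked, cat39)
  stuck <- inst
  stuck$state <- "stuck"
  notice <- coping_notice(stuck, props, on = "2026-01-08")
  expect_equal(notice$reason, "coping")
  # alternatives come from the top proposals minus the stuck mission itself
  expect_setequal(attr(notice, "alternatives"),
                  setdiff(props$mission_id, "nuts_l1"))
  expect_gte(length(attr(notice, "alternatives")), 1L)
})
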