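test_that("the shipped catalogue has 13 groups x 3 levels = 39 missions", {
  expect_equal(nrow(cat39), 39L)
  expect_length(attr(cat39, "food_groups"), 13L)
  counts <- table(cat39$food_group_id, cat39$level)
  expect_true(all(counts == 1L))
  expect_setequal(unique(cat39$food_group_id), gl$food_group_id)
  # every advanced mission requires the matching beginner one
  l2 <- cat39[cat39$level == 2L, ]
  expect_equal(l2$prereq_mission_id, sub("_l2$", "_l1", l2$mission_id))
})

test_that("catalogue loading rejects wrong cardinalities by name", {
  raw <- yaml::read_yaml(system.file("extdata", "missions.yaml",
                                     package = "nutrimission"))
  drop_nuts3 <- raw
  drop_nuts3$missions <- purrr::discard(
    drop_nuts3$missions, function(m) m$mission_id == "nuts_l3")
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(drop_nuts3, f)
  expect_error(load_catalogue(f), "\\(nuts, 3\\)")

  dup <- raw
  dup$missions <- c(dup$missions, dup$missions[4])
  f2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(dup, f2)
  expect_error(load_catalogue(f2), "duplicated|unexpected")
})

test_that("mission level follows serving bands and completion promotions", {
  expect_equal(mission_level_for("nuts", 2, character(), cat39, gl), 1L)
  expect_equal(mission_level_for("nuts", 0, character(), cat39, gl), 1L)
  expect_equal(mission_level_for("nuts", 1, character(), cat39, gl), 1L)
  expect_equal(mission_level_for("nuts", 2, "nuts_l1", cat39, gl), 2L)
  expect_equal(mission_level_for("nuts", 2, c("nuts_l1", "nuts_l2"), cat39, gl), 3L)
  expect_equal(mission_level_for("nuts", 4, character(), cat39, gl), 3L)
  # promotion never exceeds expert
  expect_equal(
    mission_level_for("nuts", 4, c("nuts_l1", "nuts_l2", "nuts_l3"), cat39, gl),
    3L
  )
  expect_error(mission_level_for("cake", 1, character(), cat39, gl),
               "not in catalogue")
})

test_that("ranking sorts by score with the documented tie-breaks", {
  # descending score: fruits 9 beats nuts 3 is mirrored by worst-first ordering
  prof <- profile_with(c(fruits = 0, nuts = 5))
  board <- score_profile(prof, gl)
  ranked <- rank_candidates(board, prof, cat39, gl)
  expect_equal(ranked$food_group_id[1], "fruits")
  expect_lt(match("fruits", ranked$food_group_id),
            match("nuts", ranked$food_group_id))
  # ranks are 1..n without gaps and a permutation of eligible groups
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_setequal(ranked$food_group_id, gl$food_group_id)

  # exhaustive tie-break oracle on the groups tied at score 10:
  # max_score ties resolve by liked first, then configured order
  tied_groups <- c("sugary_foods", "red_meat", "processed_meat")
  servings10 <- setNames(rep(8, 3), tied_groups)
  for (liked in tied_groups) {
    p <- profile_with(servings10, liked = liked)
    r <- rank_candidates(score_profile(p, gl), p, cat39, gl)
    top3 <- r$food_group_id[1:3]
    expect_equal(top3[1], liked)
    expect_equal(top3[-1],
                 intersect(attr(cat39, "food_groups"), setdiff(tied_groups, liked)))
  }
})

test_that("groups completed at expert level drop out of the ranking", {
  prof <- profile_with(c(fruits = 0),
                       completed = c("fruits_l1", "fruits_l2", "fruits_l3"))
  ranked <- rank_candidates(score_profile(prof, gl), prof, cat39, gl)
  expect_false("fruits" %in% ranked$food_group_id)
})

test_that("proposals are the top-3 prefix of the ranking", {
  prof <- profile_with(c(fruits = 0, vegetables = 0, nuts = 0, salt = 10))
  ranked <- rank_candidates(score_profile(prof, gl), prof, cat39, gl)
  props <- propose_missions(ranked, cat39)
  expect_equal(nrow(props), 3L)
  expect_equal(props$food_group_id, ranked$food_group_id[1:3])
  expect_equal(props$level, ranked$level[1:3])
  # truncation floor with fewer candidates
  short <- ranked[1:2, ]
  expect_equal(nrow(propose_missions(short, cat39)), 2L)
  expect_warning(propose_missions(ranked[0, ], cat39), "empty ranking")
})

test_that("proposed missions always match the profile's serving band", {
  set.seed(303)
  for (i in 1:30) {
    prof <- random_profile()
    ranked <- rank_candidates(score_profile(prof, gl), prof, cat39, gl)
    props <- propose_missions(ranked, cat39)
    for (j in seq_len(nrow(props))) {
      g <- props$food_group_id[j]
      expect_equal(
        props$level[j],
        mission_level_for(g, prof$weekly_servings[[g]],
                          prof$completed_missions, cat39, gl),
        label = paste("proposal", g)
      )
    }
  }
})

test_that("mission lifecycle enforces one active mission and legal transitions", {
  spec <- cat39[cat39$mission_id == "nuts_l1", ]
  inst <- start_mission(spec, "u1", on = "2026-01-05")
  expect_equal(inst$state, "active")
  expect_equal(inst$progress, 0L)

  # a second concurrent activation is rejected
  expect_error(start_mission(spec, "u1", on = "2026-01-06", current = inst),
               "already has an active mission")

  # switching abandons the old instance and emits the event
  sw <- switch_mission(inst, cat39[cat39$mission_id == "fruits_l1", ],
                       on = "2026-01-07")
  expect_equal(sw$old$state, "abandoned")
  expect_equal(sw$new$state, "active")
  expect_equal(sw$event$event_type, "mission_switched")
  expect_error(switch_mission(sw$old, spec), "cannot switch")
})

test_that("compliance logging increments progress and respects state", {
  spec <- cat39[cat39$mission_id == "nuts_l1", ]
  inst <- start_mission(spec, "u1", on = "2026-01-05")
  for (d in 6:8) inst <- log_compliance(inst, sprintf("2026-01-%02d", d))
  expect_equal(inst$progress, 3L)
  expect_equal(inst$progress, nrow(inst$compliance_log))

  done <- on_completion(inst, profile_with(), cat39, gl)
  expect_error(log_compliance(done$instance, "2026-01-09"), "completed")
})

test_that("progress evaluation distinguishes completed, stuck, expired, ongoing", {
  spec <- cat39[cat39$mission_id == "nuts_l1", ] # target 3, limit 7 days
  inst <- start_mission(spec, "u1", on = "2026-01-05")

  expect_equal(evaluate_progress(inst, "2026-01-06"), "ongoing")
  # no compliance for stuck_after_days consecutive days
  expect_equal(evaluate_progress(inst, "2026-01-08", stuck_after_days = 3), "stuck")
  # sliding window: a log two days ago keeps it ongoing
  inst2 <- log_compliance(inst, "2026-01-07")
  expect_equal(evaluate_progress(inst2, "2026-01-09", stuck_after_days = 3), "ongoing")
  expect_equal(evaluate_progress(inst2, "2026-01-10", stuck_after_days = 3), "stuck")
  # expiry past the time limit without completion
  expect_equal(evaluate_progress(inst2, "2026-01-13"), "expired")
  # completion once the target is reached mid-window
  inst3 <- inst
  for (d in 6:8) inst3 <- log_compliance(inst3, sprintf("2026-01-%02d", d))
  expect_equal(evaluate_progress(inst3, "2026-01-10"), "completed")
})

test_that("completion levels up within the group, then moves on", {
  prof <- profile_with(c(nuts = 0))
  spec <- cat39[cat39$mission_id == "nuts_l1", ]
  inst <- start_mission(spec, "u1", on = "2026-01-05")
  for (d in 6:8) inst <- log_compliance(inst, sprintf("2026-01-%02d", d))

  res <- on_completion(inst, prof, cat39, gl)
  expect_equal(res$instance$state, "completed")
  expect_true("nuts_l1" %in% res$profile$completed_missions)
  expect_equal(length(res$profile$completed_missions),
               length(prof$completed_missions) + 1L)
  expect_equal(res$proposals$mission_id[1], "nuts_l2")
  expect_match(res$notice, "Congratulations")

  # finishing the expert level proposes a different food group
  prof3 <- res$profile
  prof3$completed_missions <- c("nuts_l1", "nuts_l2")
  inst3 <- start_mission(cat39[cat39$mission_id == "nuts_l3", ], "u1",
                         on = "2026-01-12")
  for (d in 13:15) inst3 <- log_compliance(inst3, sprintf("2026-01-%02d", d))
  res3 <- on_completion(inst3, prof3, cat39, gl)
  expect_false("nuts" %in% res3$proposals$food_group_id)
  expect_error(on_completion(start_mission(spec, "u2"), prof, cat39, gl),
               "target not reached")
})
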