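# Shared fixtures built once per test run: shipped configs and small helpers.
gl <- load_guidelines()
cat39 <- load_catalogue()
repo <- build_repository(cat39)
sch_full <- ffq_schema("full")
sch_short <- ffq_schema("short")

# A complete FFQ response with a constant weekly count per item.
uniform_response <- function(count = 1, period = "week", schema = sch_full) {
  tibble::tibble(item_id = schema$items$item_id, count = count, period = period)
}

# A profile whose weekly servings are set per food group (defaults to the
# recommended lower bound so everything scores 0), bypassing item splitting.
profile_with <- function(servings = NULL, liked = character(),
                         completed = character(), prefs = dietary_prefs()) {
  base <- setNames(gl$rec_lo, gl$food_group_id)
  base[names(servings)] <- servings
  resp <- tibble::tibble(
    item_id = sch_full$items$item_id,
    count = 0, period = "week"
  )
  prof <- build_profile(resp, prefs, sch_full, user_id = "test_user",
                        liked_groups = liked, assessed_on = "2026-01-05")
  prof$weekly_servings[names(base)] <- base
  prof$completed_missions <- completed
  prof
}

# A random complete profile drawn uniformly over plausible serving ranges.
random_profile <- function() {
  resp <- tibble::tibble(
    item_id = sch_full$items$item_id,
    count = stats::runif(20, 0, 4),
    period = sample(c("day", "week", "month"), 20, replace = TRUE,
                    prob = c(0.2, 0.6, 0.2))
  )
  build_profile(resp, dietary_prefs(), sch_full, user_id = "rand_user",
                assessed_on = "2026-01-05")
}

simple_sim_user <- function(latent = 1, compliance_prob = 1,
                            responsiveness = 1, report_noise_sd = 0) {
  lat <- if (length(latent) == 1L) {
    setNames(rep(latent, nrow(gl)), gl$food_group_id)
  } else {
    latent
  }
  list(user_id = "sim_test", latent_weekly = lat,
       compliance_prob = compliance_prob, responsiveness = responsiveness,
       report_noise_sd = report_noise_sd, coeliac = FALSE,
       vegetarian_type = "none")
}
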