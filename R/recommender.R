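#' Build the motivational recommendation repository
#'
#' The repository holds three kinds of motivational content: *Did you know…?*
#' tips (one food group each, educational), general healthy-eating
#' recommendations (not tied to missions), and mission-linked recommendations
#' (tips, ideas and recipes supporting one specific mission, delivered in a
#' curated order). The shipped composition is 10 mission-linked entries per
#' mission (390 in total), 3 tips per food group, and 80 general entries —
#' over 500 recommendations. Every entry is tagged with the dietary
#' preferences it suits; the first entry of every pool suits all preferences,
#' so no user is ever left without content. Text is generated placeholder
#' prose: composition is normative, wording is meant to be replaced by
#' nutrition experts.
#'
#' @param catalogue A [load_catalogue()] table.
#' @param n_per_mission Mission-linked entries per mission (default 10).
#' @param n_did_you_know Tips per food group (default 3).
#' @param n_general General entries (default 80).
#' @return A `rec_repository` tibble: `rec_id`, `rec_type`, `title`,
#'   `sentence`, `food_group_id`, `mission_id`, `order_index`,
#'   `dietary_tags` (list column), `time_slot`.
#' @examples
#' repo <- build_repository(load_catalogue())
#' table(repo$rec_type)
#' @export
build_repository <- function(catalogue = load_catalogue(), n_per_mission = 10L,
                             n_did_you_know = 3L, n_general = 80L) {
  all_tags <- c("omnivore", "vegan", "ovo_vegetarian",
                "lacto_ovo_vegetarian", "gluten_free")
  # Deterministic tag rotation; index 1 of every pool suits every preference.
  tags_for <- function(i) {
    if (i == 1L) return(all_tags)
    out <- "omnivore"
    if (i %% 2L == 0L) out <- c(out, "gluten_free")
    if (i %% 3L == 0L) out <- c(out, "vegan", "ovo_vegetarian",
                                "lacto_ovo_vegetarian")
    if (i %% 3L == 1L) out <- c(out, "lacto_ovo_vegetarian")
    unique(out)
  }
  slots <- c("morning", "midday", "evening")
  mission_recs <- purrr::map_dfr(seq_len(nrow(catalogue)), function(k) {
    m <- catalogue[k, ]
    tibble(
      rec_id = sprintf("rec_%s_%02d", m$mission_id, seq_len(n_per_mission)),
      rec_type = "mission_linked",
      title = sprintf("Step %d for '%s'", seq_len(n_per_mission), m$title),
      sentence = sprintf(
        "Practical idea %d to help you with the %s mission (level %d).",
        seq_len(n_per_mission), m$food_group_id, m$level
      ),
      food_group_id = m$food_group_id,
      mission_id = m$mission_id,
      order_index = seq_len(n_per_mission),
      dietary_tags = purrr::map(seq_len(n_per_mission), tags_for),
      time_slot = ifelse(seq_len(n_per_mission) %% 4L == 0L,
                         slots[(seq_len(n_per_mission) %/% 4L - 1L) %% 3L + 1L],
                         NA_character_)
    )
  })
  groups <- attr(catalogue, "food_groups") %||% unique(catalogue$food_group_id)
  dyk_recs <- purrr::map_dfr(groups, function(g) {
    tibble(
      rec_id = sprintf("rec_dyk_%s_%02d", g, seq_len(n_did_you_know)),
      rec_type = "did_you_know",
      title = sprintf("Did you know? (%s, %d)", g, seq_len(n_did_you_know)),
      sentence = sprintf(
        "An evidence-based fact %d about the health effects of %s.",
        seq_len(n_did_you_know), g
      ),
      food_group_id = g,
      mission_id = NA_character_,
      order_index = NA_integer_,
      dietary_tags = purrr::map(seq_len(n_did_you_know), tags_for),
      time_slot = NA_character_
    )
  })
  general_recs <- tibble(
    rec_id = sprintf("rec_gen_%03d", seq_len(n_general)),
    rec_type = "general",
    title = sprintf("Healthy habit %d", seq_len(n_general)),
    sentence = sprintf(
      "General advice %d on meal planning, cooking techniques or mindful eating.",
      seq_len(n_general)
    ),
    food_group_id = NA_character_,
    mission_id = NA_character_,
    order_index = NA_integer_,
    dietary_tags = purrr::map(seq_len(n_general), tags_for),
    time_slot = NA_character_
  )
  repo <- bind_rows(mission_recs, dyk_recs, general_recs)
  structure(repo, class = c("rec_repository", class(repo)))
}

#' Load a recommendation repository from JSON
#'
#' @param path Path to a JSON document: an array of recommendation objects
#'   with the fields of [build_repository()].
#' @param catalogue Catalogue used to validate composition.
#' @return A validated `rec_repository` tibble.
#' @export
load_repository <- function(path, catalogue = load_catalogue()) {
  raw <- jsonlite::read_json(path)
  repo <- purrr::map_dfr(raw, function(r) {
    tibble(
      rec_id = r$rec_id,
      rec_type = r$rec_type,
      title = r$title %||% NA_character_,
      sentence = r$sentence %||% NA_character_,
      food_group_id = r$food_group_id %||% NA_character_,
      mission_id = r$mission_id %||% NA_character_,
      order_index = as.integer(r$order_index %||% NA_integer_),
      dietary_tags = list(unlist(r$dietary_tags)),
      time_slot = r$time_slot %||% NA_character_
    )
  })
  repo <- structure(repo, class = c("rec_repository", class(repo)))
  viol <- validate_repository(repo, catalogue)
  if (nrow(viol)) {
    abort(paste0("invalid recommendation repository: ",
                 paste(viol$message, collapse = "; ")))
  }
  repo
}

#' Validate repository composition
#'
#' Checks the composition constraints: more than 500 recommendations overall,
#' exactly 390 mission-linked entries (10 per mission over 39 missions), at
#' least one mission-linked entry per mission, at least one tip per food
#' group, mission-linked entries carrying a mission id and order index, and
#' tips carrying a food group.
#'
#' @param repo A `rec_repository`.
#' @param catalogue A [load_catalogue()] table.
#' @return A tibble of violations (`check`, `message`); zero rows when valid.
#' @export
validate_repository <- function(repo, catalogue = load_catalogue()) {
  v <- list()
  add <- function(check, message) {
    v[[length(v) + 1L]] <<- tibble(check = check, message = message)
  }
  counts <- table(factor(repo$rec_type,
                         levels = c("did_you_know", "general", "mission_linked")))
  if (nrow(repo) <= 500L) {
    add("total", sprintf("repository must exceed 500 entries, found %d (%s)",
                         nrow(repo),
                         paste(names(counts), counts, sep = "=", collapse = ", ")))
  }
  ml <- repo[repo$rec_type == "mission_linked", ]
  if (nrow(ml) != 390L) {
    add("mission_linked_count",
        sprintf("expected 390 mission-linked entries, found %d", nrow(ml)))
  }
  if (any(is.na(ml$mission_id))) {
    add("mission_linked_id", "mission-linked entries must carry a mission_id")
  }
  if (any(is.na(ml$order_index))) {
    add("order_index", "mission-linked entries must carry an order_index")
  }
  uncovered <- setdiff(catalogue$mission_id, ml$mission_id)
  if (length(uncovered)) {
    add("mission_coverage",
        paste0("missions without recommendations: ", toString(uncovered)))
  }
  dyk <- repo[repo$rec_type == "did_you_know", ]
  if (any(is.na(dyk$food_group_id))) {
    add("did_you_know_group", "tips must carry a food_group_id")
  }
  groups <- attr(catalogue, "food_groups") %||% unique(catalogue$food_group_id)
  nogroup <- setdiff(groups, dyk$food_group_id)
  if (length(nogroup)) {
    add("tip_coverage", paste0("food groups without tips: ", toString(nogroup)))
  }
  if (anyDuplicated(repo$rec_id)) {
    add("rec_id", "rec_id values must be unique")
  }
  if (length(v)) bind_rows(v) else tibble(check = character(), message = character())
}

#' Filter recommendations by dietary preference
#'
#' A recommendation is eligible when its tags include every restriction the
#' user's preferences imply: coeliac users require the `gluten_free` tag;
#' vegans require `vegan`; ovo- and lacto-ovo-vegetarians require their own
#' tag or `vegan` (vegan content is suitable for any vegetarian diet). Users
#' without restrictions see the whole repository.
#'
#' @param repo A `rec_repository`.
#' @param prefs A [dietary_prefs()] object.
#' @return The eligible subset of `repo`.
#' @export
eligible_recommendations <- function(repo, prefs) {
  stopifnot(inherits(prefs, "dietary_prefs"))
  keep_row <- map_lgl(repo$dietary_tags, function(tags) {
    if (prefs$coeliac && !"gluten_free" %in% tags) return(FALSE)
    switch(prefs$vegetarian_type,
      none = TRUE,
      vegan = "vegan" %in% tags,
      ovo_vegetarian = any(c("ovo_vegetarian", "vegan") %in% tags),
      lacto_ovo_vegetarian = any(c("lacto_ovo_vegetarian", "vegan") %in% tags)
    )
  })
  repo[keep_row, ]
}

# Seeded no-repeat rotation over a pool of rec ids: within equal order_index
# (or for unordered pools), a seeded permutation; the pool restarts once
# exhausted so long horizons never run dry.
pool_sequence <- function(ids, order_index, n, seed) {
  if (!length(ids)) return(character())
  perm <- with_seed(seed, {
    ord <- order(order_index %||% rep(1L, length(ids)),
                 sample.int(length(ids)))
    ids[ord]
  })
  rep(perm, length.out = n)
}

#' Schedule motivational notifications for an active mission
#'
#' Implements the delivery cadence: on the mission's first day the user gets a
#' one-time *Did you know…?* tip about the mission's food group; from then on
#' a mission-linked recommendation arrives every two days (days 2, 4 and 6 of
#' each 7-day block, in ascending curated order, then seeded rotation without
#' repeats until the pool is exhausted); and one general recommendation
#' arrives per block (on day 5, shifted one day later if that day is taken).
#' At most one notification is delivered per day, and any steady-state week
#' carries 3-4 notifications, matching the intended weekly volume.
#'
#' @param instance An active `mission_instance`.
#' @param prefs The user's [dietary_prefs()].
#' @param repo A `rec_repository`.
#' @param horizon_days Number of days to schedule (day 0 = start date).
#' @param seed Integer seed controlling within-pool rotation.
#' @return A `notification_schedule` tibble: `day` (offset from start),
#'   `date`, `rec_id`, `reason` (`mission_start_tip`, `mission_cadence`,
#'   `weekly_general`).
#' @examples
#' cat39 <- load_catalogue(); repo <- build_repository(cat39)
#' inst <- start_mission(cat39[1, ], "u1", "2026-01-05")
#' build_schedule(inst, dietary_prefs(), repo, horizon_days = 7, seed = 1)
#' @export
build_schedule <- function(instance, prefs, repo, horizon_days, seed = 1L) {
  stopifnot(inherits(instance, "mission_instance"), horizon_days >= 1)
  if (instance$state != "active") {
    abort("schedules are built for active missions only")
  }
  pool <- eligible_recommendations(repo, prefs)
  days <- integer()
  recs <- character()
  reasons <- character()
  take <- function(day, rec, reason) {
    if (length(rec) == 1L && !is.na(rec)) {
      days <<- c(days, day)
      recs <<- c(recs, rec)
      reasons <<- c(reasons, reason)
    } else {
      warn(sprintf("no eligible recommendation for %s slot on day %d",
                   reason, day))
    }
  }
  # day 0: one-time onboarding tip about the mission's food group
  dyk <- pool[pool$rec_type == "did_you_know" &
                pool$food_group_id == instance$food_group_id, ]
  if (horizon_days >= 1L) {
    tip <- pool_sequence(dyk$rec_id, NULL, 1L, seed)
    take(0L, if (length(tip)) tip else NA_character_, "mission_start_tip")
  }
  # mission-linked every two days within each week: days 2, 4, 6 of every
  # 7-day block, keeping the steady-state weekly total at 3 + 1 general
  all_days <- seq_len(horizon_days) - 1L
  cadence_days <- all_days[all_days %% 7L %in% c(2L, 4L, 6L) & all_days >= 2L]
  ml <- pool[pool$rec_type == "mission_linked" &
               pool$mission_id == instance$mission_id, ]
  ml_seq <- pool_sequence(ml$rec_id, ml$order_index, length(cadence_days),
                          seed + 1L)
  for (i in seq_along(cadence_days)) {
    take(cadence_days[i],
         if (length(ml_seq) >= i) ml_seq[i] else NA_character_,
         "mission_cadence")
  }
  # one general per 7-day block, on block day 5, +1 day on collision
  gen_days <- integer()
  for (block_start in seq(0L, horizon_days - 1L, by = 7L)) {
    d <- block_start + 5L
    if (d %in% days) d <- d + 1L
    if (d < horizon_days && d >= block_start) gen_days <- c(gen_days, d)
  }
  gen <- pool[pool$rec_type == "general", ]
  gen_seq <- pool_sequence(gen$rec_id, NULL, length(gen_days), seed + 2L)
  for (i in seq_along(gen_days)) {
    take(gen_days[i],
         if (length(gen_seq) >= i) gen_seq[i] else NA_character_,
         "weekly_general")
  }
  ord <- order(days)
  out <- tibble(day = days[ord], date = instance$started_on + days[ord],
                rec_id = recs[ord], reason = reasons[ord])
  stopifnot(!anyDuplicated(out$day))
  structure(out, class = c("notification_schedule", class(out)),
            mission_id = instance$mission_id, seed = seed)
}

#' Coping notification for a stuck mission
#'
#' When a user stops making progress, the coping-planning strategy offers
#' alternative missions to switch to, drawn from the current top proposals
#' excluding the stuck mission itself.
#'
#' @param instance A `mission_instance` in state `stuck`.
#' @param alternatives A tibble of alternative mission specs (at least one).
#' @param on Notification date.
#' @return A one-row `notification_schedule`-like tibble with reason `coping`
#'   and the alternative mission ids as an attribute.
#' @export
coping_notice <- function(instance, alternatives, on = Sys.Date()) {
  stopifnot(inherits(instance, "mission_instance"))
  if (instance$state != "stuck") {
    abort("coping notices apply to stuck missions only")
  }
  alternatives <- alternatives[alternatives$mission_id != instance$mission_id, ]
  if (nrow(alternatives) == 0L) {
    abort("at least one alternative mission is required for a coping notice")
  }
  out <- tibble(
    day = NA_integer_,
    date = as.Date(on),
    rec_id = NA_character_,
    reason = "coping",
    message = sprintf(
      "Struggling with '%s'? You could switch to: %s.",
      instance$mission_id, paste(alternatives$title, collapse = "; ")
    )
  )
  structure(out, alternatives = alternatives$mission_id)
}
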