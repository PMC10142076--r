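#' Load and validate the mission catalogue
#'
#' The catalogue holds 39 gamified dietary missions: 13 food groups with three
#' levels each (1 beginner, 2 advanced, 3 expert). Each mission has a
#' compliance target (button presses) and a time limit; advanced missions
#' require completion of the beginner mission of the same group.
#'
#' @param path Path to a catalogue YAML document; defaults to the shipped one.
#' @return A `mission_catalogue` tibble: `mission_id`, `food_group_id`,
#'   `level`, `title`, `description`, `target_count`, `time_limit_days`,
#'   `prereq_mission_id`, `elig_lo`, `elig_hi` (explicit eligibility band in
#'   servings/week, `NA` when derived from guideline status levels). The food
#'   group order is kept as the `food_groups` attribute and used as the final
#'   ranking tie-break.
#' @examples
#' cat39 <- load_catalogue()
#' nrow(cat39)
#' @export
load_catalogue <- function(path = NULL) {
  path <- path %||% nutri_extdata("missions.yaml")
  raw <- yaml::read_yaml(path)
  specs <- purrr::map_dfr(raw$missions, function(m) {
    tibble(
      mission_id = m$mission_id,
      food_group_id = m$food_group_id,
      level = as.integer(m$level),
      title = m$title,
      description = m$description,
      target_count = as.integer(m$target_count %||% 3L),
      time_limit_days = as.integer(m$time_limit_days %||% 7L),
      prereq_mission_id = m$prereq_mission_id %||% NA_character_,
      elig_lo = as.numeric(m$eligibility$lo %||% NA_real_),
      elig_hi = as.numeric(m$eligibility$hi %||% NA_real_)
    )
  })
  groups <- unlist(raw$food_groups)
  problems <- character()
  if (length(groups) != 13L) {
    problems <- c(problems, sprintf("expected 13 food groups, found %d", length(groups)))
  }
  want <- tidyr::expand_grid(food_group_id = groups, level = 1:3)
  have <- specs[, c("food_group_id", "level")]
  missing <- anti_join(want, have, by = c("food_group_id", "level"))
  extra <- anti_join(have, want, by = c("food_group_id", "level"))
  dup <- have[duplicated(have), , drop = FALSE]
  if (nrow(missing)) {
    problems <- c(problems, paste0("missing (group, level) pairs: ",
      paste(sprintf("(%s, %d)", missing$food_group_id, missing$level), collapse = ", ")))
  }
  if (nrow(extra)) {
    problems <- c(problems, paste0("unexpected (group, level) pairs: ",
      paste(sprintf("(%s, %d)", extra$food_group_id, extra$level), collapse = ", ")))
  }
  if (nrow(dup)) {
    problems <- c(problems, paste0("duplicated (group, level) pairs: ",
      paste(sprintf("(%s, %d)", dup$food_group_id, dup$level), collapse = ", ")))
  }
  if (nrow(specs) != 39L && !length(problems)) {
    problems <- sprintf("expected 39 missions, found %d", nrow(specs))
  }
  if (any(specs$target_count < 1L) || any(specs$time_limit_days < 1L)) {
    problems <- c(problems, "target_count and time_limit_days must be positive")
  }
  if (length(problems)) {
    abort(paste0("invalid mission catalogue: ", paste(problems, collapse = "; ")))
  }
  structure(specs, class = c("mission_catalogue", class(specs)),
            food_groups = groups)
}

catalogue_spec <- function(catalogue, mission_id) {
  i <- match(mission_id, catalogue$mission_id)
  if (is.na(i)) abort(paste0("unknown mission: ", mission_id))
  catalogue[i, ]
}

#' Mission level for a food group given intake and history
#'
#' The base level is the group's three-level adherence status from the scoring
#' system (poor intake puts the user in the beginner mission, good intake in
#' the expert one). When the mission at that level has already been completed,
#' the user is promoted one level (an advanced mission requires the beginner
#' one done first), never beyond expert.
#'
#' @param food_group_id Food group identifier.
#' @param servings Current weekly servings for the group.
#' @param history Character vector of completed mission ids.
#' @param catalogue A [load_catalogue()] table.
#' @inheritParams score_food_group
#' @return Integer mission level in `1:3`.
#' @examples
#' gl <- load_guidelines(); cat39 <- load_catalogue()
#' mission_level_for("nuts", 2, character(), cat39, gl)          # 1
#' mission_level_for("nuts", 2, "nuts_l1", cat39, gl)            # 2
#' mission_level_for("nuts", 4, character(), cat39, gl)          # 3
#' @export
mission_level_for <- function(food_group_id, servings, history,
                              catalogue = load_catalogue(),
                              guidelines = load_guidelines()) {
  if (!food_group_id %in% attr(catalogue, "food_groups")) {
    abort(paste0("food group not in catalogue: ", food_group_id))
  }
  score <- score_food_group(servings, food_group_id, guidelines)
  level <- assign_status_level(score, food_group_id, guidelines)
  specs <- catalogue[catalogue$food_group_id == food_group_id, ]
  while (level < 3L &&
         specs$mission_id[match(level, specs$level)] %in% history) {
    level <- level + 1L
  }
  level
}

# Does a (group, level) mission apply to this intake/history? Explicit bands
# from the catalogue win; otherwise the band implied by mission_level_for.
mission_eligible <- function(spec, servings, history, catalogue, guidelines) {
  if (!is.na(spec$elig_lo)) {
    in_band <- servings >= spec$elig_lo & servings < spec$elig_hi
    prereq_ok <- is.na(spec$prereq_mission_id) ||
      spec$prereq_mission_id %in% history
    return(in_band && prereq_ok)
  }
  mission_level_for(spec$food_group_id, servings, history,
                    catalogue, guidelines) == spec$level
}

#' Rank food-group mission candidates from a scoreboard
#'
#' Food groups are ranked from highest to lowest score (largest deviation
#' first), so the most relevant dietary change leads the list. Ties are broken
#' by group priority (`max_score` descending), then liked groups first, then
#' the configured group order. Groups whose expert mission is already
#' completed are excluded. Each candidate carries the mission level the user
#' should work at.
#'
#' @param board A [score_profile()] scoreboard.
#' @param profile The `user_profile` (supplies completion history and liked
#'   groups).
#' @inheritParams mission_level_for
#' @return A `ranked_candidates` tibble: `rank`, `food_group_id`, `level`,
#'   `score`, `max_score`, `liked`.
#' @export
rank_candidates <- function(board, profile, catalogue = load_catalogue(),
                            guidelines = load_guidelines()) {
  stopifnot(inherits(board, "nutri_scoreboard"))
  groups <- attr(catalogue, "food_groups")
  missing <- setdiff(groups, board$food_group_id)
  if (length(missing)) {
    abort(paste0("scoreboard missing catalogue groups: ", toString(missing)))
  }
  history <- profile$completed_missions
  done_expert <- catalogue$food_group_id[catalogue$level == 3L &
                                           catalogue$mission_id %in% history]
  keep_rows <- board$food_group_id %in% groups &
    !board$food_group_id %in% done_expert
  g <- board$food_group_id[keep_rows]
  score <- board$score[keep_rows]
  max_score <- board$max_score[keep_rows]
  # base level from the scoreboard; promotion when that level's mission of the
  # group is already completed (same semantics as mission_level_for)
  level <- board$level[keep_rows]
  mission_of <- setNames(catalogue$mission_id,
                         paste(catalogue$food_group_id, catalogue$level))
  for (i in seq_along(g)) {
    while (level[i] < 3L &&
           mission_of[[paste(g[i], level[i])]] %in% history) {
      level[i] <- level[i] + 1L
    }
  }
  liked <- g %in% profile$liked_groups
  ord <- order(-score, -max_score, -liked, match(g, groups))
  ranked <- tibble(
    rank = seq_along(ord),
    food_group_id = g[ord],
    level = level[ord],
    score = score[ord],
    max_score = max_score[ord],
    liked = liked[ord]
  )
  structure(ranked, class = c("ranked_candidates", class(ranked)))
}

#' Propose the top missions from a ranking
#'
#' The first three candidates of the ranked list (fewer if fewer exist) are
#' translated into their mission specs and shown to the user to pick one.
#'
#' @param ranked A [rank_candidates()] table.
#' @inheritParams mission_level_for
#' @param n Number of proposals (default 3).
#' @return A tibble of mission specs, a prefix of the ranking.
#' @export
propose_missions <- function(ranked, catalogue = load_catalogue(), n = 3L) {
  if (nrow(ranked) == 0L) {
    warn("empty ranking: no missions to propose")
    return(catalogue[0, ])
  }
  k <- seq_len(min(n, nrow(ranked)))
  idx <- match(paste(ranked$food_group_id[k], ranked$level[k]),
               paste(catalogue$food_group_id, catalogue$level))
  out <- as_tibble(catalogue)[idx, ]
  structure(out, class = c("mission_catalogue", class(out)),
            food_groups = attr(catalogue, "food_groups"))
}

#' Mission lifecycle
#'
#' A mission instance tracks one user working one mission: state
#' (`proposed`, `active`, `completed`, `stuck`, `abandoned`), start date,
#' compliance log, and progress. Only one mission may be active per user at a
#' time; switching abandons the old instance. Valid transitions are
#' proposed -> active -> completed / stuck / abandoned and stuck -> active /
#' abandoned.
#'
#' @param spec One-row mission spec from the catalogue.
#' @param user_id User identifier.
#' @param on Start date.
#' @param current The user's current `mission_instance`, if any; starting
#'   while another mission is active is an error.
#' @return A `mission_instance` object.
#' @examples
#' cat39 <- load_catalogue()
#' inst <- start_mission(cat39[cat39$mission_id == "nuts_l1", ], "u1", "2026-01-05")
#' inst$state
#' @export
start_mission <- function(spec, user_id, on = Sys.Date(), current = NULL) {
  stopifnot(nrow(spec) == 1L)
  if (!is.null(current) && current$state %in% c("active", "stuck")) {
    abort("user already has an active mission; switch or abandon it first")
  }
  structure(
    list(
      instance_id = sprintf("%s_%s_%s", user_id, spec$mission_id,
                            format(as.Date(on))),
      mission_id = spec$mission_id,
      food_group_id = spec$food_group_id,
      level = spec$level,
      user_id = user_id,
      state = "active",
      started_on = as.Date(on),
      target_count = spec$target_count,
      time_limit_days = spec$time_limit_days,
      compliance_log = tibble(date = as.Date(character()), increment = integer()),
      progress = 0L
    ),
    class = "mission_instance"
  )
}

#' @rdname start_mission
#' @param instance The active `mission_instance` to switch away from.
#' @param new_spec One-row spec of the replacement mission.
#' @return For `switch_mission()`: a list with `old` (abandoned instance),
#'   `new` (freshly active instance), and `event` (a `mission_switched`
#'   [engine_event()]).
#' @export
switch_mission <- function(instance, new_spec, on = Sys.Date()) {
  stopifnot(inherits(instance, "mission_instance"))
  if (!instance$state %in% c("active", "stuck")) {
    abort(paste0("cannot switch from a ", instance$state, " mission"))
  }
  instance$state <- "abandoned"
  new_inst <- start_mission(new_spec, instance$user_id, on = on)
  list(
    old = instance,
    new = new_inst,
    event = engine_event("mission_switched",
                         payload = list(from = instance$mission_id,
                                        to = new_inst$mission_id),
                         occurred_at = as.Date(on))
  )
}

#' Log a compliance button press
#'
#' Each press records one healthy action toward the active mission (e.g. one
#' healthy sandwich eaten) and increments progress by one.
#'
#' @param instance An active `mission_instance`.
#' @param date Date of the press.
#' @return The updated instance.
#' @export
log_compliance <- function(instance, date = Sys.Date()) {
  stopifnot(inherits(instance, "mission_instance"))
  if (instance$state != "active") {
    abort(paste0("cannot log compliance on a ", instance$state, " mission"))
  }
  instance$compliance_log <- tibble(
    date = c(instance$compliance_log$date, as.Date(date)),
    increment = c(instance$compliance_log$increment, 1L)
  )
  instance$progress <- sum(instance$compliance_log$increment)
  instance
}

#' Evaluate mission progress at a checkpoint
#'
#' @param instance An active `mission_instance`.
#' @param today Evaluation date.
#' @param stuck_after_days Days without any compliance event before the
#'   mission counts as stuck (default 3).
#' @return One of `"completed"` (target reached), `"stuck"` (no compliance
#'   event in the last `stuck_after_days` days), `"expired"` (time limit
#'   passed without completion), or `"ongoing"`.
#' @export
evaluate_progress <- function(instance, today = Sys.Date(), stuck_after_days = 3L) {
  stopifnot(inherits(instance, "mission_instance"))
  if (instance$state != "active") {
    abort(paste0("cannot evaluate a ", instance$state, " mission"))
  }
  today <- as.Date(today)
  if (instance$progress >= instance$target_count) return("completed")
  if (as.numeric(today - instance$started_on) > instance$time_limit_days) {
    return("expired")
  }
  last_event <- if (nrow(instance$compliance_log)) {
    max(instance$compliance_log$date)
  } else {
    instance$started_on
  }
  if (as.numeric(today - last_event) >= stuck_after_days) return("stuck")
  "ongoing"
}

set_mission_state <- function(instance, state) {
  edges <- list(
    proposed = c("active"),
    active = c("completed", "stuck", "abandoned"),
    stuck = c("active", "abandoned"),
    completed = character(),
    abandoned = character()
  )
  if (!state %in% edges[[instance$state]]) {
    abort(sprintf("illegal mission state transition %s -> %s",
                  instance$state, state))
  }
  instance$state <- state
  instance
}

#' Handle mission completion: level up and re-propose
#'
#' Marks the mission completed in the user's history, re-scores the profile,
#' and proposes what to work on next: the next level of the same food group if
#' one exists, otherwise the top of a fresh ranking over the remaining groups.
#' A congratulation notice accompanies the level-up.
#'
#' @param instance A `mission_instance` whose target has been reached.
#' @param profile The user's `user_profile`.
#' @inheritParams mission_level_for
#' @return A list with `instance` (state `completed`), `profile` (history
#'   updated), `board` (fresh scoreboard), `proposals` (next mission specs),
#'   and `notice` (congratulation text).
#' @export
on_completion <- function(instance, profile, catalogue = load_catalogue(),
                          guidelines = load_guidelines()) {
  stopifnot(inherits(instance, "mission_instance"),
            inherits(profile, "user_profile"))
  if (instance$progress < instance$target_count) {
    abort("mission target not reached; nothing to complete")
  }
  instance <- set_mission_state(instance, "completed")
  profile$completed_missions <- union(profile$completed_missions,
                                      instance$mission_id)
  board <- score_profile(profile, guidelines)
  same_group_next <- catalogue[catalogue$food_group_id == instance$food_group_id &
                                 catalogue$level == instance$level + 1L, ]
  proposals <- if (nrow(same_group_next)) {
    same_group_next
  } else {
    ranked <- rank_candidates(board, profile, catalogue, guidelines)
    propose_missions(ranked, catalogue)
  }
  notice <- sprintf(
    "Congratulations! You completed '%s' and levelled up in %s.",
    instance$mission_id, instance$food_group_id
  )
  list(instance = instance, profile = profile, board = board,
       proposals = proposals, notice = notice)
}

#' @export
print.mission_instance <- function(x, ...) {
  cat(sprintf(
    "<mission_instance %s: %s, progress %d/%d, started %s>\n",
    x$mission_id, x$state, x$progress, x$target_count, format(x$started_on)
  ))
  invisible(x)
}

#' @rdname start_mission
#' @param x A `mission_instance`.
#' @param ... Unused.
#' @method tidy mission_instance
#' @export
tidy.mission_instance <- function(x, ...) {
  tibble(
    instance_id = x$instance_id,
    mission_id = x$mission_id,
    food_group_id = x$food_group_id,
    level = x$level,
    user_id = x$user_id,
    state = x$state,
    started_on = x$started_on,
    progress = x$progress,
    target_count = x$target_count
  )
}
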