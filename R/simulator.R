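#' Simulation configuration
#'
#' Defines the synthetic population: latent weekly servings per food group are
#' drawn log-normally around group medians describing a typical improvable
#' diet (low fruit/vegetable/nuts/wholegrain intake, frequent sugary,
#' processed and ultra-processed foods), with behavioural parameters for
#' compliance (probability of pressing the mission button on a given day),
#' responsiveness (weekly fractional move of true intake toward the
#' recommended target while working a mission), and FFQ reporting noise.
#'
#' @param medians Named numeric vector of latent median servings/week per food
#'   group.
#' @param sdlog Log-scale standard deviation of the latent draws.
#' @param compliance_prob Daily probability of logging compliance.
#' @param responsiveness Weekly fraction moved toward the dietary target.
#' @param report_noise_sd Gaussian sd of FFQ reporting noise (servings/week).
#' @param p_coeliac,p_vegetarian Prevalence of dietary restrictions.
#' @return A `sim_config` list.
#' @export
sim_config <- function(medians = c(
                         fruits = 7, vegetables = 7, pulses = 2, nuts = 1,
                         water = 21, wholegrains = 3, olive_oil = 7, fish = 2,
                         salt = 5, sugary_foods = 6, red_meat = 4,
                         processed_meat = 4, ultraprocessed = 4
                       ),
                       sdlog = 0.5, compliance_prob = 0.9,
                       responsiveness = 0.5, report_noise_sd = 0.5,
                       p_coeliac = 0.05, p_vegetarian = 0.1) {
  stopifnot(all(medians >= 0), sdlog >= 0,
            compliance_prob >= 0, compliance_prob <= 1,
            responsiveness >= 0, responsiveness <= 1, report_noise_sd >= 0)
  structure(list(medians = medians, sdlog = sdlog,
                 compliance_prob = compliance_prob,
                 responsiveness = responsiveness,
                 report_noise_sd = report_noise_sd,
                 p_coeliac = p_coeliac, p_vegetarian = p_vegetarian),
            class = "sim_config")
}

#' Generate a reproducible synthetic user cohort
#'
#' @param n Number of users (at least 1).
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed always yields the same cohort.
#' @return A `sim_cohort` tibble: `user_id`, `latent_weekly` (list of named
#'   numeric vectors), `compliance_prob`, `responsiveness`, `report_noise_sd`,
#'   `coeliac`, `vegetarian_type`, `seed` (per-user sub-seed).
#' @examples
#' cohort <- generate_cohort(5, sim_config(), seed = 1)
#' cohort$user_id
#' @export
generate_cohort <- function(n, config = sim_config(), seed = 1L) {
  if (!is.numeric(n) || n < 1) abort("cohort size n must be at least 1")
  n <- as.integer(n)
  groups <- names(config$medians)
  with_seed(seed, {
    latents <- purrr::map(seq_len(n), function(i) {
      setNames(
        rlnorm(length(groups), meanlog = log(pmax(config$medians, 1e-6)),
               sdlog = config$sdlog),
        groups
      )
    })
    veg_types <- c("vegan", "ovo_vegetarian", "lacto_ovo_vegetarian")
    cohort <- tibble(
      user_id = sprintf("sim_user_%04d", seq_len(n)),
      latent_weekly = latents,
      compliance_prob = config$compliance_prob,
      responsiveness = config$responsiveness,
      report_noise_sd = config$report_noise_sd,
      coeliac = runif(n) < config$p_coeliac,
      vegetarian_type = ifelse(runif(n) < config$p_vegetarian,
                               sample(veg_types, n, replace = TRUE), "none"),
      seed = sample.int(2^31 - 1, n)
    )
    structure(cohort, class = c("sim_cohort", class(cohort)))
  })
}

#' Simulate answering an FFQ
#'
#' Each schema item reports the user's latent weekly servings for its food
#' group (split evenly across the group's items) plus Gaussian reporting
#' noise, clamped at zero. Reports use the weekly period; counts stay
#' fractional, matching household-measure bands like "2-3 per week".
#'
#' @param user A one-row `sim_cohort` slice or a list with `latent_weekly` and
#'   `report_noise_sd`.
#' @param schema An [ffq_schema()].
#' @param seed Integer seed.
#' @return A response tibble (`item_id`, `count`, `period`).
#' @export
respond_ffq <- function(user, schema = ffq_schema(), seed = 1L) {
  user <- as_sim_user(user)
  items <- schema$items
  shares <- items |>
    as_tibble() |>
    group_by(.data$food_group_id) |>
    mutate(share = unname(user$latent_weekly[.data$food_group_id[1]]) / dplyr::n()) |>
    ungroup()
  with_seed(seed, {
    noise <- rnorm(nrow(shares), sd = user$report_noise_sd)
    tibble(
      item_id = shares$item_id,
      count = pmax(0, shares$share + noise),
      period = "week"
    )
  })
}

as_sim_user <- function(user) {
  if (is.data.frame(user)) {
    stopifnot(nrow(user) == 1L)
    user <- as.list(user)
    user$latent_weekly <- user$latent_weekly[[1L]]
  }
  stopifnot(!is.null(user$latent_weekly))
  user$report_noise_sd <- user$report_noise_sd %||% 0
  user
}

# Weekly-serving target the behaviour-update rule moves toward: the midpoint
# of the recommended interval, or one serving inside an unbounded one.
target_servings <- function(entry) {
  if (is.finite(entry$rec_hi)) (entry$rec_lo + entry$rec_hi) / 2 else entry$rec_lo + 1
}

#' Simulate one user working the intervention loop
#'
#' Runs the full engine-in-the-loop day simulation: the user answers the full
#' FFQ on day 0, receives the ranked top-3 missions and starts the first one;
#' each day scheduled notifications are delivered and the user logs compliance
#' with probability `compliance_prob`; completed missions trigger level-up and
#' the next proposal (next level of the same group when it exists); missing
#' progress triggers stuck detection and a coping notice; expired missions are
#' re-proposed; on compliant weeks the latent intake of the active mission's
#' food group moves toward its recommended target by the responsiveness
#' fraction; and every 28 days a short FFQ refreshes the profile.
#'
#' @param user One `sim_cohort` row (or equivalent list with `user_id`,
#'   `latent_weekly`, `compliance_prob`, `responsiveness`, `report_noise_sd`,
#'   `coeliac`, `vegetarian_type`).
#' @param days Number of days to simulate (at least 1).
#' @param seed Integer seed for all randomness in the trace.
#' @inheritParams mission_level_for
#' @param repo A `rec_repository`.
#' @param start_date Calendar date of day 0.
#' @param stuck_after_days Stuck-detection window (see [evaluate_progress()]).
#' @return A `sim_trace` tibble with one row per simulated day: `day`, `date`,
#'   `mission_id`, `mission_state`, `progress`, `complied`,
#'   `n_notifications`, `events` (comma-separated), `first_group_level`
#'   (status level of the first-proposed food group under the current
#'   profile), and `latent` (list of latent snapshots). Attributes carry the
#'   initial scoreboard, the first proposals and the final profile.
#' @export
simulate_user <- function(user, days, seed = 1L,
                          guidelines = load_guidelines(),
                          catalogue = load_catalogue(),
                          repo = build_repository(catalogue),
                          start_date = as.Date("2026-01-05"),
                          stuck_after_days = 3L) {
  stopifnot(days >= 1)
  user <- as_sim_user(user)
  prefs <- dietary_prefs(
    coeliac = isTRUE(user$coeliac),
    vegetarian_type = user$vegetarian_type %||% "none"
  )
  schema_full <- ffq_schema("full")
  schema_short <- ffq_schema("short")
  day0 <- as.Date(start_date)
  latent <- user$latent_weekly
  targets <- setNames(
    map_dbl(seq_len(nrow(guidelines)), function(i) target_servings(guidelines[i, ])),
    guidelines$food_group_id
  )

  # dietary filtering is preference-static: filter the pool once per user
  pool <- eligible_recommendations(repo, prefs)

  response <- respond_ffq(user, schema_full, seed = seed)
  profile <- build_profile(response, prefs, schema_full,
                           user_id = user$user_id %||% "sim_user",
                           assessed_on = day0)
  board0 <- score_profile(profile, guidelines)
  ranked <- rank_candidates(board0, profile, catalogue, guidelines)
  proposals <- propose_missions(ranked, catalogue)
  first_group <- ranked$food_group_id[1L]
  instance <- start_mission(proposals[1L, ], profile$user_id, on = day0)
  schedule <- build_schedule(instance, prefs, pool,
                             horizon_days = days + 1L, seed = seed + 1L)
  first_entry <- guideline_entry(guidelines, first_group)
  first_level <- function() {
    sc <- lookup_score(profile$weekly_servings[[first_group]],
                       first_entry$score_table[[1L]])
    if (sc > first_entry$poor_above) 1L else if (sc < first_entry$good_below) 3L else 2L
  }

  tr_mission <- character(days); tr_state <- character(days)
  tr_progress <- integer(days); tr_complied <- logical(days)
  tr_notif <- integer(days); tr_events <- character(days)
  tr_level <- integer(days); tr_latent <- vector("list", days)
  complied_groups <- character()

  with_seed(seed + 2L, {
    for (d in seq_len(days)) {
      date <- day0 + d
      events <- character()
      n_notif <- sum(schedule$date == date)
      complied <- FALSE
      if (instance$state == "active") {
        complied <- runif(1) < (user$compliance_prob %||% 0)
        if (complied) {
          instance <- log_compliance(instance, date)
          complied_groups <- union(complied_groups, instance$food_group_id)
          events <- c(events, "compliance_logged")
        }
        status <- evaluate_progress(instance, date, stuck_after_days)
        if (status == "completed") {
          res <- on_completion(instance, profile, catalogue, guidelines)
          profile <- res$profile
          events <- c(events, "mission_completed")
          nxt <- res$proposals[1L, ]
          instance <- start_mission(nxt, profile$user_id, on = date)
          schedule <- build_schedule(instance, prefs, pool,
                                     horizon_days = days - d + 1L,
                                     seed = seed + 2L + d)
          events <- c(events, paste0("started:", instance$mission_id))
        } else if (status == "stuck") {
          instance <- set_mission_state(instance, "stuck")
          board <- score_profile(profile, guidelines)
          alts <- propose_missions(
            rank_candidates(board, profile, catalogue, guidelines), catalogue
          )
          alts <- alts[alts$mission_id != instance$mission_id, ]
          if (nrow(alts)) {
            coping_notice(instance, alts, on = date)
            n_notif <- n_notif + 1L
            events <- c(events, "coping_notice")
          }
          # the user keeps trying the same mission after the nudge
          instance <- set_mission_state(instance, "active")
        } else if (status == "expired") {
          # treated as stuck with a re-proposal: switch to the top alternative
          board <- score_profile(profile, guidelines)
          alts <- propose_missions(
            rank_candidates(board, profile, catalogue, guidelines), catalogue
          )
          sw <- switch_mission(instance, alts[1L, ], on = date)
          instance <- sw$new
          schedule <- build_schedule(instance, prefs, pool,
                                     horizon_days = days - d + 1L,
                                     seed = seed + 2L + d)
          events <- c(events, "mission_switched",
                      paste0("started:", instance$mission_id))
        }
      }
      # weekly behaviour update on compliant weeks (conserves other groups)
      if (d %% 7L == 0L) {
        for (g in complied_groups) {
          latent[g] <- latent[g] +
            (user$responsiveness %||% 0) * (targets[[g]] - latent[g])
        }
        complied_groups <- character()
      }
      # monthly short FFQ refreshes the reported profile
      if (d %% 28L == 0L) {
        u2 <- user
        u2$latent_weekly <- latent
        short_resp <- respond_ffq(u2, schema_short, seed = seed + 100L + d)
        profile <- apply_short_ffq(profile, short_resp, schema_short,
                                   assessed_on = date)
        events <- c(events, "questionnaire_completed")
      }
      tr_mission[d] <- instance$mission_id
      tr_state[d] <- instance$state
      tr_progress[d] <- instance$progress
      tr_complied[d] <- complied
      tr_notif[d] <- n_notif
      tr_events[d] <- paste(events, collapse = ",")
      tr_level[d] <- first_level()
      tr_latent[[d]] <- latent
    }
  })
  trace <- tibble(
    day = seq_len(days), date = day0 + seq_len(days),
    mission_id = tr_mission, mission_state = tr_state,
    progress = tr_progress, complied = tr_complied,
    n_notifications = tr_notif, events = tr_events,
    first_group_level = tr_level, latent = tr_latent
  )
  structure(trace,
            class = c("sim_trace", class(trace)),
            user_id = profile$user_id,
            first_group = first_group,
            board0 = board0,
            proposals0 = proposals,
            profile = profile)
}

#' Simulate a cohort and summarise behaviour change
#'
#' Runs [simulate_user()] for every cohort member and reports, per user, the
#' adherence status level of their first-proposed food group on day 0 and on
#' the final day, plus engagement counts.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @inheritParams simulate_user
#' @return A `cohort_summary` tibble: `user_id`, `first_group`, `level_day0`,
#'   `level_final`, `n_completed`, `n_notifications`.
#' @export
simulate_cohort <- function(cohort, days, seed = 1L,
                            guidelines = load_guidelines(),
                            catalogue = load_catalogue(),
                            repo = build_repository(catalogue),
                            start_date = as.Date("2026-01-05"),
                            stuck_after_days = 3L) {
  out <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    tr <- simulate_user(cohort[i, ], days = days, seed = cohort$seed[i],
                        guidelines = guidelines, catalogue = catalogue,
                        repo = repo, start_date = start_date,
                        stuck_after_days = stuck_after_days)
    board0 <- attr(tr, "board0")
    fg <- attr(tr, "first_group")
    tibble(
      user_id = attr(tr, "user_id"),
      first_group = fg,
      level_day0 = board0$level[board0$food_group_id == fg],
      level_final = tr$first_group_level[nrow(tr)],
      n_completed = length(attr(tr, "profile")$completed_missions),
      n_notifications = sum(tr$n_notifications)
    )
  })
  structure(out, class = c("cohort_summary", class(out)))
}

#' @method glance sim_trace
#' @export
glance.sim_trace <- function(x, ...) {
  tibble(
    user_id = attr(x, "user_id"),
    days = nrow(x),
    first_group = attr(x, "first_group"),
    level_day0 = attr(x, "board0")$level[
      attr(x, "board0")$food_group_id == attr(x, "first_group")],
    level_final = x$first_group_level[nrow(x)],
    n_complied = sum(x$complied),
    n_completed = length(attr(x, "profile")$completed_missions),
    n_notifications = sum(x$n_notifications)
  )
}
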