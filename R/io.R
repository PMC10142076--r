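#' Read and write engine state as JSON
#'
#' The engine persists a single-user session between invocations: the user
#' profile, the current mission instance, the notification history and the
#' event log. All dates serialize as ISO-8601 strings; `load_state()` after
#' [save_state()] reproduces the state exactly.
#'
#' @param profile A `user_profile` (or `NULL`).
#' @param instance A `mission_instance` (or `NULL`).
#' @param notifications A notification tibble (`date`, `rec_id`, `reason`).
#' @param events A tibble of engine events (`date`, `event_type`, `detail`).
#' @return A `session_state` list.
#' @export
session_state <- function(profile = NULL, instance = NULL,
                          notifications = empty_notifications(),
                          events = empty_events()) {
  structure(list(profile = profile, instance = instance,
                 notifications = notifications, events = events),
            class = "session_state")
}

empty_notifications <- function() {
  tibble(date = as.Date(character()), rec_id = character(), reason = character())
}

empty_events <- function() {
  tibble(date = as.Date(character()), event_type = character(), detail = character())
}

#' @rdname session_state
#' @param state A `session_state`.
#' @param path File path for the state JSON document.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "session_state"))
  doc <- list(
    profile = if (!is.null(state$profile)) profile_to_list(state$profile),
    instance = if (!is.null(state$instance)) instance_to_list(state$instance),
    notifications = df_to_list(state$notifications),
    events = df_to_list(state$events)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname session_state
#' @export
load_state <- function(path) {
  doc <- jsonlite::read_json(path)
  session_state(
    profile = if (!is.null(doc$profile)) profile_from_list(doc$profile),
    instance = if (!is.null(doc$instance)) instance_from_list(doc$instance),
    notifications = list_to_df(doc$notifications, empty_notifications()),
    events = list_to_df(doc$events, empty_events())
  )
}

profile_to_list <- function(p) {
  list(
    user_id = p$user_id,
    weekly_servings = as.list(p$weekly_servings),
    preferences = list(coeliac = p$preferences$coeliac,
                       vegetarian_type = p$preferences$vegetarian_type),
    liked_groups = as.list(p$liked_groups),
    completed_missions = as.list(p$completed_missions),
    last_assessed = format(p$last_assessed)
  )
}

profile_from_list <- function(x) {
  new_user_profile(
    user_id = x$user_id,
    weekly_servings = unlist(x$weekly_servings),
    preferences = dietary_prefs(coeliac = isTRUE(x$preferences$coeliac),
                                vegetarian_type = x$preferences$vegetarian_type),
    liked_groups = as.character(unlist(x$liked_groups)),
    completed_missions = as.character(unlist(x$completed_missions)),
    last_assessed = as.Date(x$last_assessed)
  )
}

instance_to_list <- function(i) {
  list(
    instance_id = i$instance_id, mission_id = i$mission_id,
    food_group_id = i$food_group_id, level = i$level, user_id = i$user_id,
    state = i$state, started_on = format(i$started_on),
    target_count = i$target_count, time_limit_days = i$time_limit_days,
    compliance_log = df_to_list(
      mutate(i$compliance_log, date = format(.data$date))),
    progress = i$progress
  )
}

instance_from_list <- function(x) {
  log <- list_to_df(x$compliance_log,
                    tibble(date = character(), increment = integer()))
  structure(
    list(
      instance_id = x$instance_id, mission_id = x$mission_id,
      food_group_id = x$food_group_id, level = as.integer(x$level),
      user_id = x$user_id, state = x$state,
      started_on = as.Date(x$started_on),
      target_count = as.integer(x$target_count),
      time_limit_days = as.integer(x$time_limit_days),
      compliance_log = mutate(log, date = as.Date(.data$date),
                              increment = as.integer(.data$increment)),
      progress = as.integer(x$progress)
    ),
    class = "mission_instance"
  )
}

df_to_list <- function(df) {
  is_date <- vapply(df, function(c) inherits(c, "Date"), TRUE)
  df[is_date] <- lapply(df[is_date], format)
  purrr::map(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}

list_to_df <- function(x, template) {
  if (is.null(x) || !length(x)) return(template)
  out <- purrr::map_dfr(x, as_tibble)
  if ("date" %in% names(out)) out$date <- as.Date(out$date)
  out
}

#' Export a compliance log or notification schedule as CSV
#'
#' @param x A data frame (compliance log, schedule, or simulation trace).
#' @param path Output CSV path.
#' @export
write_log_csv <- function(x, path) {
  x <- as_tibble(x)
  x <- x[!vapply(x, is.list, TRUE)]
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Validate all shipped configuration documents
#'
#' Runs every configuration validator: guideline tables, mission catalogue
#' cardinality, and repository composition.
#'
#' @inheritParams rank_candidates
#' @param repo A `rec_repository`.
#' @return A tibble of violations across validators (zero rows when all
#'   configurations are valid).
#' @export
validate_configs <- function(guidelines = load_guidelines(),
                             catalogue = load_catalogue(),
                             repo = build_repository(catalogue)) {
  gv <- validate_guidelines(guidelines)
  rv <- validate_repository(repo, catalogue)
  out <- bind_rows(
    if (nrow(gv)) mutate(gv, validator = "guidelines"),
    if (nrow(rv)) mutate(rv, food_group_id = NA_character_,
                         validator = "repository")
  )
  if (!nrow(out)) {
    out <- tibble(check = character(), food_group_id = character(),
                  message = character(), validator = character())
  }
  out
}
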