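#' Load a food-frequency questionnaire schema
#'
#' The full schema has 20 items, each mapped to one of the 13 scored food
#' groups, with representative foods and a household-measure portion
#' description. The short schema is the monthly follow-up variant: a subset of
#' the full items that still covers every food group, so a short response can
#' refresh the whole profile.
#'
#' @param version `"full"` (20 items) or `"short"` (the monthly subset).
#' @param path Path to a schema JSON document; defaults to the shipped schema.
#' @return An `ffq_schema` object: a list with `schema_id`, `version`, and an
#'   `items` tibble (`item_id`, `food_group_id`, `label`,
#'   `representative_foods`, `portion_description`).
#' @examples
#' sch <- ffq_schema()
#' nrow(sch$items)
#' @export
ffq_schema <- function(version = c("full", "short"), path = NULL) {
  version <- match.arg(version)
  path <- path %||% nutri_extdata("ffq_schema.json")
  raw <- jsonlite::read_json(path)
  items <- purrr::map_dfr(raw$items, function(it) {
    tibble(
      item_id = it$item_id,
      food_group_id = it$food_group_id,
      label = it$label,
      representative_foods = list(unlist(it$representative_foods)),
      portion_description = it$portion_description
    )
  })
  if (anyDuplicated(items$item_id)) {
    abort("FFQ schema items must have unique item_id values")
  }
  if (version == "full" && nrow(items) != 20L) {
    abort(sprintf("full FFQ schema must have exactly 20 items, found %d", nrow(items)))
  }
  if (version == "short") {
    short_ids <- unlist(raw$short_items)
    if (length(short_ids) == 0L) abort("short FFQ schema must be non-empty")
    missing <- setdiff(short_ids, items$item_id)
    if (length(missing)) {
      abort(paste0("short FFQ items not in full schema: ", toString(missing)))
    }
    items <- items[match(short_ids, items$item_id), ]
  }
  structure(
    list(
      schema_id = if (version == "full") raw$schema_id else paste0(raw$schema_id, "_short"),
      version = version,
      items = items
    ),
    class = "ffq_schema"
  )
}

#' @export
print.ffq_schema <- function(x, ...) {
  cat(sprintf(
    "<ffq_schema %s: %s, %d items, %d food groups>\n",
    x$schema_id, x$version, nrow(x$items), dplyr::n_distinct(x$items$food_group_id)
  ))
  invisible(x)
}

#' Dietary preferences
#'
#' Captures the dietary-habits questionnaire: coeliac status and vegetarian
#' diet type. These drive which motivational recommendations a user may
#' receive.
#'
#' @param coeliac Logical flag.
#' @param vegetarian_type One of `"none"`, `"vegan"`, `"ovo_vegetarian"`,
#'   `"lacto_ovo_vegetarian"`.
#' @return A `dietary_prefs` list.
#' @examples
#' dietary_prefs(coeliac = TRUE, vegetarian_type = "vegan")
#' @export
dietary_prefs <- function(coeliac = FALSE,
                          vegetarian_type = c("none", "vegan", "ovo_vegetarian",
                                              "lacto_ovo_vegetarian")) {
  vegetarian_type <- match.arg(vegetarian_type)
  stopifnot(is.logical(coeliac), length(coeliac) == 1L, !is.na(coeliac))
  structure(list(coeliac = coeliac, vegetarian_type = vegetarian_type),
            class = "dietary_prefs")
}

#' Convert a reported eating frequency to servings per week
#'
#' FFQ responses report an average count per day, week, or month; all
#' downstream scoring works in servings/week. Daily counts multiply by 7;
#' monthly counts use the calendar-exact 12/52 factor (12 months = 52 weeks).
#'
#' @param count Non-negative reported frequency (non-integers allowed, e.g.
#'   2.5 for "2-3 times").
#' @param period `"day"`, `"week"`, or `"month"`. Vectorised over both
#'   arguments.
#' @return Servings per week, same length as `count`.
#' @examples
#' normalize_frequency(1, "day")    # 7
#' normalize_frequency(13, "month") # 3
#' @export
normalize_frequency <- function(count, period) {
  if (any(is.na(count)) || any(count < 0)) {
    abort("FFQ counts must be non-negative and non-missing")
  }
  bad <- setdiff(unique(period), c("day", "week", "month"))
  if (length(bad)) {
    abort(paste0("unknown FFQ period unit: ", toString(bad)))
  }
  factor <- c(day = 7, week = 1, month = 12 / 52)[period]
  unname(count * factor)
}

#' Build a behavioural user profile from a full FFQ response
#'
#' Aggregates a complete 20-item FFQ response into weekly servings per food
#' group (summing items that share a group) and attaches the dietary
#' preferences. The result is the behavioural-status view of the user that the
#' scoring system consumes.
#'
#' @param response A data frame with columns `item_id`, `count`, `period`
#'   covering every item of `schema` exactly once.
#' @param prefs A [dietary_prefs()] object.
#' @param schema The full [ffq_schema()].
#' @param user_id Identifier for the user.
#' @param liked_groups Optional character vector of preferred food groups,
#'   used as a ranking tie-break.
#' @param assessed_on Date of the response (`Date` or ISO-8601 string).
#' @return A `user_profile` object with `weekly_servings` (named numeric over
#'   all food groups), `preferences`, `liked_groups`, `completed_missions`,
#'   `last_assessed`.
#' @examples
#' sch <- ffq_schema()
#' resp <- tibble::tibble(item_id = sch$items$item_id, count = 1, period = "week")
#' build_profile(resp, dietary_prefs(), sch, user_id = "u1")
#' @export
build_profile <- function(response, prefs, schema = ffq_schema(),
                          user_id = "user", liked_groups = character(),
                          assessed_on = Sys.Date()) {
  stopifnot(inherits(schema, "ffq_schema"))
  response <- validate_response(response, schema, require_complete = TRUE)
  per_item <- response |>
    mutate(weekly = normalize_frequency(.data$count, .data$period)) |>
    left_join(schema$items[, c("item_id", "food_group_id")], by = "item_id")
  groups <- unique(schema$items$food_group_id)
  weekly <- per_item |>
    group_by(.data$food_group_id) |>
    summarise(weekly = sum(.data$weekly), .groups = "drop")
  servings <- setNames(rep(0, length(groups)), groups)
  servings[weekly$food_group_id] <- weekly$weekly
  new_user_profile(
    user_id = user_id,
    weekly_servings = servings,
    preferences = prefs,
    liked_groups = liked_groups,
    completed_missions = character(),
    last_assessed = as.Date(assessed_on)
  )
}

new_user_profile <- function(user_id, weekly_servings, preferences,
                             liked_groups, completed_missions, last_assessed) {
  stopifnot(all(weekly_servings >= 0), !is.null(names(weekly_servings)))
  structure(
    list(
      user_id = user_id,
      weekly_servings = weekly_servings,
      preferences = preferences,
      liked_groups = liked_groups,
      completed_missions = completed_missions,
      last_assessed = last_assessed
    ),
    class = "user_profile"
  )
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf(
    "<user_profile %s: %d food groups, %d completed missions, assessed %s>\n",
    x$user_id, length(x$weekly_servings), length(x$completed_missions),
    format(x$last_assessed)
  ))
  print(tidy(x), ...)
  invisible(x)
}

#' Update a profile from a monthly short-FFQ response
#'
#' The short FFQ captures one-month progression: only the food groups covered
#' by the short schema are overwritten with the new weekly servings; all other
#' fields (preferences, completion history, untouched groups) are preserved,
#' and `last_assessed` is refreshed.
#'
#' @param profile A `user_profile`.
#' @param response Data frame with `item_id`, `count`, `period` covering the
#'   short schema.
#' @param schema The short [ffq_schema()].
#' @param assessed_on Date of the short response.
#' @return The updated `user_profile`.
#' @export
apply_short_ffq <- function(profile, response, schema = ffq_schema("short"),
                            assessed_on = Sys.Date()) {
  stopifnot(inherits(profile, "user_profile"), inherits(schema, "ffq_schema"))
  if (nrow(schema$items) == 0L) abort("short FFQ schema must be non-empty")
  response <- validate_response(response, schema, require_complete = TRUE)
  per_item <- response |>
    mutate(weekly = normalize_frequency(.data$count, .data$period)) |>
    left_join(schema$items[, c("item_id", "food_group_id")], by = "item_id")
  upd <- per_item |>
    group_by(.data$food_group_id) |>
    summarise(weekly = sum(.data$weekly), .groups = "drop")
  profile$weekly_servings[upd$food_group_id] <- upd$weekly
  profile$last_assessed <- as.Date(assessed_on)
  profile
}

# Shared response validation: schema membership, duplicates, completeness.
validate_response <- function(response, schema, require_complete = TRUE) {
  response <- as_tibble(response)
  needed <- c("item_id", "count", "period")
  missing_cols <- setdiff(needed, names(response))
  if (length(missing_cols)) {
    abort(paste0("FFQ response missing columns: ", toString(missing_cols)))
  }
  outside <- setdiff(response$item_id, schema$items$item_id)
  if (length(outside)) {
    abort(paste0("FFQ response has items outside the schema: ", toString(outside)))
  }
  dup <- unique(response$item_id[duplicated(response$item_id)])
  if (length(dup)) {
    abort(paste0("FFQ response has duplicated items: ", toString(dup)))
  }
  if (require_complete) {
    absent <- setdiff(schema$items$item_id, response$item_id)
    if (length(absent)) {
      abort(paste0("FFQ response missing items: ", toString(absent)))
    }
  }
  response
}

#' @rdname build_profile
#' @param x A `user_profile`.
#' @param ... Unused.
#' @method tidy user_profile
#' @export
tidy.user_profile <- function(x, ...) {
  tibble(
    food_group_id = names(x$weekly_servings),
    weekly_servings = unname(x$weekly_servings)
  )
}
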