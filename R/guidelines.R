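#' Load the guideline scoring configuration
#'
#' Each food group carries a recommended weekly serving interval, a maximum
#' score encoding its priority (10 for the six highest-impact groups, 9 for
#' fruits, 8 otherwise), and a piecewise-constant score table mapping weekly
#' servings to an integer deviation score: 0 inside the recommended interval,
#' growing with distance from it. Score tables are data so nutritionists can
#' revise cutoffs without touching code.
#'
#' @param path Path to a guidelines YAML document; defaults to the shipped
#'   configuration.
#' @return A `nutri_guidelines` tibble with one row per food group: columns
#'   `food_group_id`, `label`, `direction`, `rec_lo`, `rec_hi`, `max_score`,
#'   `score_table` (list of tibbles `lo`, `hi`, `score`), `poor_above`,
#'   `good_below` (status-level bands; the global defaults unless overridden
#'   per group).
#' @examples
#' gl <- load_guidelines()
#' gl$food_group_id
#' @export
load_guidelines <- function(path = NULL) {
  path <- path %||% nutri_extdata("guidelines.yaml")
  raw <- yaml::read_yaml(path)
  bands <- raw$level_bands %||% list()
  poor_above <- bands$poor_above %||% 5
  good_below <- bands$good_below %||% 3
  entries <- purrr::map_dfr(raw$food_groups, function(e) {
    tab <- purrr::map_dfr(e$score_table, function(r) {
      tibble(lo = as.numeric(r$lo), hi = as.numeric(r$hi),
             score = as.integer(r$score))
    })
    eb <- e$level_bands %||% list()
    tibble(
      food_group_id = e$food_group_id,
      label = e$label %||% e$food_group_id,
      direction = e$direction,
      rec_lo = as.numeric(e$recommended_weekly$lo),
      rec_hi = as.numeric(e$recommended_weekly$hi),
      max_score = as.integer(e$max_score),
      score_table = list(tab),
      poor_above = as.numeric(eb$poor_above %||% poor_above),
      good_below = as.numeric(eb$good_below %||% good_below)
    )
  })
  if (anyDuplicated(entries$food_group_id)) {
    abort("guideline food_group_id values must be unique")
  }
  structure(entries, class = c("nutri_guidelines", class(entries)))
}

guideline_entry <- function(guidelines, food_group_id) {
  i <- match(food_group_id, guidelines$food_group_id)
  if (is.na(i)) {
    abort(paste0("unknown food group: ", food_group_id))
  }
  guidelines[i, ]
}

# Piecewise-constant table lookup, intervals [lo, hi) with hi = Inf allowed.
lookup_score <- function(servings, table) {
  idx <- findInterval(servings, table$lo)
  if (any(idx == 0) || any(servings >= table$hi[idx])) {
    abort("score table is not total over the requested servings value")
  }
  as.integer(table$score[idx])
}

#' Score a food group against its guideline
#'
#' Looks up the weekly servings in the group's score table. A score of 0 means
#' consumption inside the recommended interval; the maximum score (10, 9, or
#' 8 depending on the group) is reached at the table's saturating extreme,
#' e.g. more than seven weekly servings of processed meat, or zero weekly
#' servings of fruit.
#'
#' @param servings Weekly servings (non-negative scalar or vector).
#' @param food_group_id Which group to score.
#' @param guidelines A [load_guidelines()] table.
#' @return Integer score(s) in `0..max_score`.
#' @examples
#' gl <- load_guidelines()
#' score_food_group(8, "processed_meat", gl) # 10
#' score_food_group(0, "fruits", gl)         # 9
#' @export
score_food_group <- function(servings, food_group_id, guidelines = load_guidelines()) {
  if (any(is.na(servings)) || any(servings < 0)) {
    abort("servings must be non-negative and non-missing")
  }
  entry <- guideline_entry(guidelines, food_group_id)
  lookup_score(servings, entry$score_table[[1L]])
}

#' Map a score to a three-level adherence status
#'
#' Status levels gamify the score: 1 = poor, 2 = average, 3 = good. With the
#' default bands a score above 5 is poor, 3 to 5 is average, and below 3 is
#' good (so perfect adherence, score 0, is always good). Bands can be
#' overridden per food group in the guideline configuration.
#'
#' @param score Integer score(s) as returned by [score_food_group()].
#' @inheritParams score_food_group
#' @return Integer status level(s) in `1:3`.
#' @examples
#' gl <- load_guidelines()
#' assign_status_level(6, "nuts", gl) # 1 (poor)
#' assign_status_level(0, "nuts", gl) # 3 (good)
#' @export
assign_status_level <- function(score, food_group_id, guidelines = load_guidelines()) {
  entry <- guideline_entry(guidelines, food_group_id)
  if (any(score < 0) || any(score > entry$max_score)) {
    abort(sprintf("score out of range 0..%d for group %s",
                  entry$max_score, food_group_id))
  }
  ifelse(score > entry$poor_above, 1L,
         ifelse(score < entry$good_below, 3L, 2L))
}

#' Score a whole profile
#'
#' Applies [score_food_group()] and [assign_status_level()] to every
#' configured food group, producing the scoreboard that drives mission
#' ranking.
#'
#' @param profile A `user_profile` covering all guideline food groups.
#' @inheritParams score_food_group
#' @return A `nutri_scoreboard` tibble: `food_group_id`, `weekly_servings`,
#'   `score`, `max_score`, `level`, with the user id and assessment date as
#'   attributes.
#' @examples
#' sch <- ffq_schema()
#' resp <- tibble::tibble(item_id = sch$items$item_id, count = 0, period = "week")
#' prof <- build_profile(resp, dietary_prefs(), sch)
#' score_profile(prof, load_guidelines())
#' @export
score_profile <- function(profile, guidelines = load_guidelines()) {
  stopifnot(inherits(profile, "user_profile"))
  missing <- setdiff(guidelines$food_group_id, names(profile$weekly_servings))
  if (length(missing)) {
    abort(paste0("profile missing food groups: ", toString(missing)))
  }
  servings <- unname(profile$weekly_servings[guidelines$food_group_id])
  score <- vapply(seq_along(servings), function(i) {
    lookup_score(servings[i], guidelines$score_table[[i]])
  }, 0L)
  board <- tibble(
    food_group_id = guidelines$food_group_id,
    weekly_servings = servings,
    score = score,
    max_score = guidelines$max_score,
    level = ifelse(score > guidelines$poor_above, 1L,
                   ifelse(score < guidelines$good_below, 3L, 2L))
  )
  structure(board,
            class = c("nutri_scoreboard", class(board)),
            user_id = profile$user_id,
            assessed_on = profile$last_assessed)
}

#' @method glance nutri_scoreboard
#' @export
glance.nutri_scoreboard <- function(x, ...) {
  tibble(
    user_id = attr(x, "user_id"),
    assessed_on = attr(x, "assessed_on"),
    n_groups = nrow(x),
    total_score = sum(x$score),
    n_poor = sum(x$level == 1L),
    n_average = sum(x$level == 2L),
    n_good = sum(x$level == 3L)
  )
}

#' Validate a guideline configuration
#'
#' Checks the structural constraints every guideline table must satisfy:
#' the 10/9/8 maximum-score assignment over the shipped group lists, table
#' totality over `[0, Inf)`, score 0 inside the recommended interval, score
#' monotone non-decreasing with distance from the recommendation, table
#' maximum equal to `max_score`, and the nuts serving bands (0/1/2 weekly
#' servings must band to status level 1; more than 3 to level 3).
#'
#' @inheritParams score_food_group
#' @return A tibble of violations (`check`, `food_group_id`, `message`);
#'   zero rows means the configuration is valid.
#' @examples
#' nrow(validate_guidelines(load_guidelines())) # 0
#' @export
validate_guidelines <- function(guidelines = load_guidelines()) {
  v <- list()
  add <- function(check, group, message) {
    v[[length(v) + 1L]] <<- tibble(check = check, food_group_id = group,
                                   message = message)
  }
  max10 <- c("vegetables", "water", "sugary_foods", "red_meat",
             "processed_meat", "ultraprocessed")
  for (i in seq_len(nrow(guidelines))) {
    g <- guidelines$food_group_id[i]
    tab <- guidelines$score_table[[i]]
    ms <- guidelines$max_score[i]

    expected <- if (g %in% max10) 10L else if (g == "fruits") 9L else 8L
    if (ms != expected) {
      add("max_score_assignment", g,
          sprintf("max_score is %d, expected %d", ms, expected))
    }
    # totality: contiguous [lo, hi) intervals from 0 to Inf
    tab <- arrange(tab, .data$lo)
    if (tab$lo[1] != 0 || !is.infinite(tab$hi[nrow(tab)]) ||
        (nrow(tab) > 1 && any(tab$lo[-1] != tab$hi[-nrow(tab)]))) {
      add("totality", g, "score table does not cover [0, Inf) contiguously")
      next
    }
    if (max(tab$score) != ms) {
      add("max_of_table", g,
          sprintf("table maximum %d differs from max_score %d", max(tab$score), ms))
    }
    # probe grid: interval representatives plus boundaries
    finite_hi <- tab$hi[is.finite(tab$hi)]
    probes <- sort(unique(c(tab$lo, finite_hi - 1e-9,
                            max(c(tab$lo, finite_hi)) + 1)))
    sc <- lookup_score(probes, tab)
    rec_lo <- guidelines$rec_lo[i]
    rec_hi <- guidelines$rec_hi[i]
    inside <- probes >= rec_lo & probes < rec_hi
    if (any(sc[inside] != 0L)) {
      add("zero_inside_recommendation", g,
          "non-zero score inside the recommended interval")
    }
    # monotone non-decreasing with distance from the recommendation on each side
    below <- probes < rec_lo
    if (any(below) && is.unsorted(rev(sc[below]))) {
      add("monotonicity", g, "score not monotone below the recommended interval")
    }
    above <- probes >= rec_hi
    if (any(above) && is.unsorted(sc[above])) {
      add("monotonicity", g, "score not monotone above the recommended interval")
    }
    if (g == "nuts") {
      lv <- assign_status_level(lookup_score(c(0, 1, 2), tab), "nuts", guidelines)
      if (any(lv != 1L)) {
        add("nuts_band", g, "0/1/2 servings/week must give status level 1")
      }
      lv3 <- assign_status_level(lookup_score(c(3.5, 5, 10), tab), "nuts", guidelines)
      if (any(lv3 != 3L)) {
        add("nuts_band", g, "more than 3 servings/week must give status level 3")
      }
    }
  }
  if (length(v)) bind_rows(v) else {
    tibble(check = character(), food_group_id = character(), message = character())
  }
}
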