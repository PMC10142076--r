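#' Working memory for the rule engine
#'
#' The rule-based reasoner keeps the user's current state as a working memory
#' of keyed facts (e.g. `profile.servings.nuts`, `score.nuts`). Re-asserting a
#' key replaces the previous fact; each fact carries a monotonically
#' increasing assertion stamp used for recency-based conflict resolution.
#'
#' @return An empty `working_memory` object.
#' @examples
#' wm <- working_memory()
#' wm <- wm_assert(wm, "score.nuts", 8)
#' wm_get(wm, "score.nuts")
#' @export
working_memory <- function() {
  structure(list(values = list(), stamp = numeric(), counter = 0),
            class = "working_memory")
}

#' @rdname working_memory
#' @param wm A `working_memory`.
#' @param key Fact key (dot-separated identifier path).
#' @param value Any scalar or structured value.
#' @export
wm_assert <- function(wm, key, value) {
  stopifnot(inherits(wm, "working_memory"), is.character(key), length(key) == 1L)
  wm$counter <- wm$counter + 1
  wm$values[[key]] <- value
  wm$stamp[key] <- wm$counter
  wm
}

#' @rdname working_memory
#' @export
wm_retract <- function(wm, key) {
  stopifnot(inherits(wm, "working_memory"))
  hit <- if (endsWith(key, "*")) {
    startsWith(names(wm$values), sub("\\*$", "", key))
  } else {
    names(wm$values) == key
  }
  wm$values <- wm$values[!hit]
  wm$stamp <- wm$stamp[names(wm$values)]
  wm
}

#' @rdname working_memory
#' @param default Value returned when the key is absent.
#' @export
wm_get <- function(wm, key, default = NULL) {
  if (key %in% names(wm$values)) wm$values[[key]] else default
}

#' @export
print.working_memory <- function(x, ...) {
  cat(sprintf("<working_memory: %d facts>\n", length(x$values)))
  if (length(x$values)) {
    print(tibble(key = names(x$values),
                 value = map_chr(x$values, function(v) toString(format(v))),
                 asserted_at = unname(x$stamp[names(x$values)])))
  }
  invisible(x)
}

#' Define a rule
#'
#' Rules are IF-THEN productions over working-memory facts. Conditions are
#' conjunctions of simple comparisons (`eq`, `ne`, `lt`, `le`, `gt`, `ge`,
#' `in`, `present`, `absent`) on fact keys; the pseudo-key `event.type`
#' matches the dispatched event. Comparisons on absent keys fail (except
#' `absent`). Actions assert or retract facts, or emit effects (events,
#' mission proposals, notifications) collected by [dispatch()].
#'
#' @param rule_id Unique identifier.
#' @param salience Integer priority; higher fires first.
#' @param conditions List of conditions, each `list(key, op, value)` (value
#'   omitted for `present`/`absent`).
#' @param actions List of actions, each `list(type = ...)` with
#'   `type` in `assert` (`key`, `value`), `retract` (`key`, `*` wildcard
#'   suffix allowed), `emit`, `propose`, `notify` (free-form payload fields).
#' @return A `nutri_rule` list.
#' @export
rule <- function(rule_id, salience = 0L, conditions = list(), actions = list()) {
  ops <- c("eq", "ne", "lt", "le", "gt", "ge", "in", "present", "absent")
  for (cond in conditions) {
    if (!is.character(cond$key) || !cond$op %in% ops) {
      abort(sprintf("rule %s has a malformed condition", rule_id))
    }
  }
  types <- c("assert", "retract", "emit", "propose", "notify")
  for (act in actions) {
    if (!act$type %in% types) {
      abort(sprintf("rule %s has a malformed action type", rule_id))
    }
  }
  structure(list(rule_id = rule_id, salience = as.integer(salience),
                 conditions = conditions, actions = actions),
            class = "nutri_rule")
}

#' An engine event
#'
#' @param event_type One of `questionnaire_completed`, `mission_completed`,
#'   `mission_switched`, `compliance_logged`, `day_advanced`.
#' @param payload Optional named list.
#' @param occurred_at Timestamp (date or datetime).
#' @return An `engine_event` list.
#' @export
engine_event <- function(event_type, payload = list(), occurred_at = Sys.Date()) {
  allowed <- c("questionnaire_completed", "mission_completed",
               "mission_switched", "compliance_logged", "day_advanced")
  if (!event_type %in% allowed) {
    abort(paste0("unknown event_type: ", event_type))
  }
  structure(list(event_type = event_type, payload = payload,
                 occurred_at = occurred_at),
            class = "engine_event")
}

cond_holds <- function(cond, wm, event) {
  if (cond$key == "event.type") {
    val <- event$event_type
  } else if (!cond$key %in% names(wm$values)) {
    return(cond$op == "absent")
  } else {
    val <- wm$values[[cond$key]]
  }
  switch(cond$op,
    present = TRUE,
    absent = FALSE,
    eq = isTRUE(val == cond$value),
    ne = isTRUE(val != cond$value),
    lt = isTRUE(val < cond$value),
    le = isTRUE(val <= cond$value),
    gt = isTRUE(val > cond$value),
    ge = isTRUE(val >= cond$value),
    `in` = val %in% cond$value
  )
}

rule_matches <- function(r, wm, event) {
  for (cond in r$conditions) {
    if (!cond_holds(cond, wm, event)) return(FALSE)
  }
  TRUE
}

# Most-recent stamp among the rule's matched fact keys (0 if none are facts).
match_recency <- function(r, wm) {
  keys <- intersect(vapply(r$conditions, `[[`, "", "key"), names(wm$values))
  if (length(keys)) max(wm$stamp[keys]) else 0
}

#' Dispatch an event through the inference engine
#'
#' Forward-chains the rule base over working memory until quiescence: in each
#' cycle the eligible matching rule with the highest salience fires (ties
#' broken by most recently asserted matched fact, then rule definition order).
#' A rule becomes refractory after firing and is eligible again only once one
#' of its matched facts has been re-asserted, so dispatch terminates when no
#' rule can add anything new; a cycle guard bounds runaway rule bases.
#'
#' @param event An [engine_event()].
#' @param wm A [working_memory()].
#' @param rules List of [rule()] objects.
#' @param effect_handlers Named list of functions, keyed by action type
#'   (`propose`, `notify`, `emit`); each is called with `(wm, action, event)`
#'   and its return value becomes the recorded effect payload. Without a
#'   handler the raw action is recorded.
#' @param max_firings Cycle guard (default 1000 firings per dispatch).
#' @return A list with `wm` (updated memory), `effects` (list of emitted
#'   effects), and `trace` (tibble of firings: `rule_id`, `order`).
#' @export
dispatch <- function(event, wm, rules, effect_handlers = list(),
                     max_firings = 1000L) {
  stopifnot(inherits(event, "engine_event"), inherits(wm, "working_memory"))
  effects <- list()
  fired <- character()
  trace <- list()
  # Refractoriness: a rule may re-fire only when one of its matched facts has
  # been (re-)asserted since its last firing; rules matching only on the event
  # fire at most once per dispatch.
  last_fire_recency <- setNames(rep(-Inf, length(rules)),
                                vapply(rules, `[[`, "", "rule_id"))
  n_fired <- 0L
  repeat {
    idx <- integer()
    rec <- numeric()
    for (k in seq_along(rules)) {
      r <- rules[[k]]
      if (!rule_matches(r, wm, event)) next
      mr <- match_recency(r, wm)
      if (is.finite(last_fire_recency[[r$rule_id]]) &&
          mr <= last_fire_recency[[r$rule_id]]) next
      idx <- c(idx, k)
      rec <- c(rec, mr)
    }
    if (!length(idx)) break
    sal <- vapply(rules[idx], `[[`, 0L, "salience")
    ord <- order(-sal, -rec)
    r <- rules[[idx[ord[1L]]]]
    n_fired <- n_fired + 1L
    if (n_fired > max_firings) {
      abort(paste0(
        "rule engine cycle guard exceeded; firing sequence: ",
        paste(utils::tail(fired, 20), collapse = " -> ")
      ))
    }
    fired <- c(fired, r$rule_id)
    trace[[n_fired]] <- tibble(rule_id = r$rule_id, order = n_fired)
    last_fire_recency[[r$rule_id]] <- rec[ord[1L]]
    for (act in r$actions) {
      if (act$type == "assert") {
        wm <- wm_assert(wm, act$key, act$value)
      } else if (act$type == "retract") {
        wm <- wm_retract(wm, act$key)
      } else {
        handler <- effect_handlers[[act$type]]
        payload <- if (is.null(handler)) act else handler(wm, act, event)
        effects[[length(effects) + 1L]] <-
          list(type = act$type, rule_id = r$rule_id, payload = payload)
      }
    }
  }
  list(wm = wm,
       effects = effects,
       trace = if (length(trace)) bind_rows(trace) else
         tibble(rule_id = character(), order = integer()))
}

#' Generate the mission-selection rule base from the guideline configuration
#'
#' The expert knowledge of the scoring system is compiled into declarative
#' rules: one scoring rule per score-table interval (matching
#' `profile.servings.<group>` against the interval and asserting
#' `score.<group>`), one banding rule per group and status level (asserting
#' `level.<group>` from the score), and a single low-salience proposal rule
#' that fires once per questionnaire event and emits a `propose` effect. The
#' behaviour is equivalent to the procedural pipeline
#' [score_profile()] + [rank_candidates()] + [propose_missions()].
#'
#' @inheritParams score_food_group
#' @return A list of [rule()] objects.
#' @export
rules_from_guidelines <- function(guidelines = load_guidelines()) {
  rules <- list()
  for (i in seq_len(nrow(guidelines))) {
    g <- guidelines$food_group_id[i]
    tab <- guidelines$score_table[[i]]
    fact <- paste0("profile.servings.", g)
    for (j in seq_len(nrow(tab))) {
      conds <- list(
        list(key = "event.type", op = "eq", value = "questionnaire_completed"),
        list(key = fact, op = "ge", value = tab$lo[j])
      )
      if (is.finite(tab$hi[j])) {
        conds <- c(conds, list(list(key = fact, op = "lt", value = tab$hi[j])))
      }
      rules[[length(rules) + 1L]] <- rule(
        rule_id = sprintf("score_%s_%d", g, j),
        salience = 10L,
        conditions = conds,
        actions = list(list(type = "assert", key = paste0("score.", g),
                            value = as.integer(tab$score[j])))
      )
    }
    score_key <- paste0("score.", g)
    level_key <- paste0("level.", g)
    pa <- guidelines$poor_above[i]
    gb <- guidelines$good_below[i]
    rules[[length(rules) + 1L]] <- rule(
      rule_id = paste0("band_", g, "_poor"), salience = 5L,
      conditions = list(list(key = score_key, op = "gt", value = pa)),
      actions = list(list(type = "assert", key = level_key, value = 1L))
    )
    rules[[length(rules) + 1L]] <- rule(
      rule_id = paste0("band_", g, "_average"), salience = 5L,
      conditions = list(list(key = score_key, op = "le", value = pa),
                        list(key = score_key, op = "ge", value = gb)),
      actions = list(list(type = "assert", key = level_key, value = 2L))
    )
    rules[[length(rules) + 1L]] <- rule(
      rule_id = paste0("band_", g, "_good"), salience = 5L,
      conditions = list(list(key = score_key, op = "lt", value = gb)),
      actions = list(list(type = "assert", key = level_key, value = 3L))
    )
  }
  rules[[length(rules) + 1L]] <- rule(
    rule_id = "propose_missions", salience = 1L,
    conditions = list(
      list(key = "event.type", op = "eq", value = "questionnaire_completed"),
      list(key = "proposal.done", op = "absent")
    ),
    actions = list(list(type = "propose"),
                   list(type = "assert", key = "proposal.done", value = TRUE))
  )
  rules
}

#' Run mission selection through the rule engine
#'
#' Loads the user's servings, completion history and liked groups into working
#' memory, dispatches a `questionnaire_completed` event through the compiled
#' rule base, and reads the proposal effect back out. This is the declarative
#' route to the same answer as the procedural
#' [score_profile()] / [rank_candidates()] / [propose_missions()] pipeline.
#'
#' @param profile A `user_profile`.
#' @inheritParams rank_candidates
#' @param rules Optional precompiled rule base from [rules_from_guidelines()].
#' @return A list with `board` (scoreboard reconstructed from rule-asserted
#'   facts), `ranked`, `proposals`, `wm`, and the firing `trace`.
#' @export
propose_via_rules <- function(profile, guidelines = load_guidelines(),
                              catalogue = load_catalogue(),
                              rules = rules_from_guidelines(guidelines)) {
  wm <- working_memory()
  for (g in names(profile$weekly_servings)) {
    wm <- wm_assert(wm, paste0("profile.servings.", g),
                    unname(profile$weekly_servings[g]))
  }
  wm <- wm_assert(wm, "profile.completed", profile$completed_missions)
  wm <- wm_assert(wm, "profile.liked", profile$liked_groups)

  result_env <- new.env(parent = emptyenv())
  handler <- list(propose = function(wm, action, event) {
    board <- board_from_wm(wm, profile, guidelines)
    ranked <- rank_candidates(board, profile, catalogue, guidelines)
    proposals <- propose_missions(ranked, catalogue)
    assign("board", board, envir = result_env)
    assign("ranked", ranked, envir = result_env)
    assign("proposals", proposals, envir = result_env)
    list(n = nrow(proposals), mission_ids = proposals$mission_id)
  })
  out <- dispatch(engine_event("questionnaire_completed"), wm, rules,
                  effect_handlers = handler)
  list(
    board = get0("board", envir = result_env),
    ranked = get0("ranked", envir = result_env),
    proposals = get0("proposals", envir = result_env),
    wm = out$wm,
    effects = out$effects,
    trace = out$trace
  )
}

# Rebuild a scoreboard from score.* / level.* facts asserted by the rules.
board_from_wm <- function(wm, profile, guidelines) {
  board <- guidelines |>
    as_tibble() |>
    transmute(
      .data$food_group_id,
      weekly_servings = unname(profile$weekly_servings[.data$food_group_id]),
      score = map_int(.data$food_group_id, function(g) {
        s <- wm_get(wm, paste0("score.", g))
        if (is.null(s)) abort(paste0("rules asserted no score for ", g))
        as.integer(s)
      }),
      max_score = .data$max_score,
      level = map_int(.data$food_group_id, function(g) {
        l <- wm_get(wm, paste0("level.", g))
        if (is.null(l)) abort(paste0("rules asserted no level for ", g))
        as.integer(l)
      })
    )
  structure(board, class = c("nutri_scoreboard", class(board)),
            user_id = profile$user_id, assessed_on = profile$last_assessed)
}
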