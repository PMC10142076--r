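#' Plot a scoreboard
#'
#' Bar chart of per-food-group deviation scores, filled by adherence status
#' level, with the group's maximum possible score marked.
#'
#' @param object A `nutri_scoreboard`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nutri_scoreboard
#' @export
autoplot.nutri_scoreboard <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(
      food_group_id = factor(.data$food_group_id,
                             levels = .data$food_group_id[order(-.data$score)]),
      status = factor(c("poor", "average", "good")[.data$level],
                      levels = c("poor", "average", "good"))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$food_group_id, y = .data$score,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$max_score), shape = 95, size = 6,
                        colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(poor = "#d95f02",
                                          average = "#e6ab02",
                                          good = "#1b9e77")) +
    ggplot2::labs(x = NULL, y = "deviation score",
                  title = "Food-group scores (dash = maximum score)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a notification schedule
#'
#' Calendar strip of scheduled notifications coloured by reason.
#'
#' @param object A `notification_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot notification_schedule
#' @export
autoplot.notification_schedule <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(week = .data$day %/% 7L, weekday = .data$day %% 7L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weekday, y = -.data$week,
                                   fill = .data$reason)) +
    ggplot2::geom_tile(colour = "white", width = 0.9, height = 0.9) +
    ggplot2::scale_x_continuous(breaks = 0:6) +
    ggplot2::labs(x = "day of week", y = "week",
                  title = "Notification cadence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a simulation trace
#'
#' Mission progress and the adherence status of the first-proposed food group
#' over simulated days.
#'
#' @param object A `sim_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_trace
#' @export
autoplot.sim_trace <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$first_group_level),
                       colour = "#1b9e77", linewidth = 0.8) +
    ggplot2::geom_point(
      data = df[df$complied, ],
      ggplot2::aes(y = 0.8), shape = 3, size = 1, colour = "grey50"
    ) +
    ggplot2::scale_y_continuous(breaks = 1:3,
                                labels = c("poor", "average", "good"),
                                limits = c(0.7, 3.1)) +
    ggplot2::labs(
      x = "day", y = "status of first-proposed group",
      title = paste0("Simulated behaviour change: ", attr(object, "first_group")),
      subtitle = "crosses: compliance button presses"
    ) +
    ggplot2::theme_minimal()
}
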