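#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the decision boundaries of the published classifier
#'
#' Heat map of the terminal SPMS probability over the EDSS grid and an age
#' range, with the implied RR/SP label.
#'
#' @param age_range Ages to display (default 15-90 years).
#' @param floor_age Passed to [classify_ms()].
#' @return A ggplot.
#' @export
plot_decision_boundary <- function(age_range = c(15, 90), floor_age = FALSE) {
  grid <- tidyr::expand_grid(
    edss = setdiff(seq(0, 10, by = 0.5), 0.5),
    age = seq(age_range[1], age_range[2], by = 0.5)
  )
  res <- classify_ms(grid$edss, grid$age, floor_age = floor_age)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$age, y = .data$edss,
                                    fill = .data$sp_probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2166ac",
                                  mid = "#f7f7f7", high = "#b2182b",
                                  limits = c(0, 1),
                                  name = "P(SPMS)") +
    ggplot2::labs(x = "Age at latest assessment (years)",
                  y = "Latest EDSS score",
                  title = "Decision boundaries of the phenotype classifier") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot
#'
#' Step curve with its 95% confidence band.
#'
#' @param object An `ms_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_km <- function(object, ...) {
  d <- tidy(object)
  d0 <- dplyr::bind_rows(
    tibble::tibble(time = 0, estimate = 1, conf.low = 1, conf.high = 1),
    dplyr::select(d, "time", "estimate", "conf.low", "conf.high")
  )
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2, fill = "#2166ac") +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (years)", y = "Free of SP conversion") +
    ggplot2::theme_minimal()
}

#' Compare time-to-SP curves across labelling methods
#'
#' @param object An `ms_tts` from [compare_time_to_sp()].
#' @param origin `"onset"` (default) or `"birth"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_tts <- function(object, origin = c("onset", "birth"), ...) {
  origin <- match.arg(origin)
  d <- tidy(object) %>% dplyr::filter(.data$origin == !!origin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate,
                                  colour = .data$method, fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = if (origin == "birth") "Age (years)" else "Time from onset (years)",
      y = "Free of SP conversion", colour = "Labeller", fill = "Labeller"
    ) +
    ggplot2::theme_minimal()
}

#' Plot metrics of a confusion summary
#'
#' Point estimates with their confidence intervals.
#'
#' @param object An `ms_confusion`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ms_confusion <- function(object, ...) {
  d <- tidy(object) %>% dplyr::filter(!is.na(.data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Proportion") +
    ggplot2::theme_minimal()
}

#' Plot a fitted tree's variable importance
#'
#' @param object An `sp_tree`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sp_tree <- function(object, ...) {
  d <- variable_importance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$variable,
                                                     .data$importance),
                                  y = .data$importance)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative importance") +
    ggplot2::theme_minimal()
}
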