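#' Plot a fitted functional response
#'
#' Mean kills per density (points, +/- one standard error) with the fitted
#' Rogers curve.
#'
#' @param object An [fit_rogers()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fr_fit <- function(object, ...) {
  obs <- object$trials |>
    dplyr::group_by(.data$n_initial) |>
    dplyr::summarise(
      mean_killed = mean(.data$n_killed),
      se = stats::sd(.data$n_killed) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  grid <- tibble::tibble(
    n_initial = seq(min(obs$n_initial), max(obs$n_initial), length.out = 200)
  )
  grid$expected <- rogers_expected_kills(grid$n_initial, object$attack_rate,
                                         object$handling_time,
                                         object$trials$duration[1])
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$n_initial)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$expected),
                       linewidth = 0.8, colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$mean_killed,
      ymin = .data$mean_killed - .data$se,
      ymax = .data$mean_killed + .data$se
    )) +
    ggplot2::labs(x = "Initial prey density", y = "Prey killed") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap confidence envelope
#'
#' Fitted functional response curve with its pointwise 95% bootstrap
#' envelope.
#'
#' @param object A [bootstrap_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fr_boot <- function(object, ...) {
  ggplot2::ggplot(object$envelope, ggplot2::aes(x = .data$n_initial)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "steelblue",
                       linewidth = 0.8) +
    ggplot2::geom_point(
      data = object$fit$trials,
      ggplot2::aes(x = .data$n_initial, y = .data$n_killed),
      alpha = 0.4
    ) +
    ggplot2::labs(x = "Initial prey density", y = "Prey killed") +
    ggplot2::theme_minimal()
}

#' Proportion-consumed diagnostic plot
#'
#' Proportion of prey killed against initial density with LOWESS trend
#' lines per group — the visual companion to [type_test()]: a falling
#' trend indicates a Type II response.
#'
#' @param trials Predator feeding trials.
#' @param span LOWESS span (see [lowess_proportions()]).
#' @param group_vars Grouping columns for separate trends.
#' @return A ggplot object.
#' @export
plot_proportions <- function(trials, span = 0.9,
                             group_vars = c("sex", "temperature", "salinity")) {
  pred <- dplyr::filter(tibble::as_tibble(trials), !.data$is_control) |>
    dplyr::mutate(proportion = .data$n_killed / .data$n_initial)
  group_vars <- intersect(group_vars, names(pred))
  grouped <- pred |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars)))
  keys <- dplyr::group_keys(grouped)
  trends <- purrr::map2_dfr(
    dplyr::group_split(grouped, .keep = TRUE), seq_len(nrow(keys)),
    function(g, i) {
      sm <- lowess_proportions(g, span = span)
      dplyr::bind_cols(keys[rep(i, nrow(sm)), , drop = FALSE], sm)
    }
  )
  label_of <- function(d) {
    do.call(paste, c(lapply(group_vars, function(v) d[[v]]), sep = "/"))
  }
  pred$group <- label_of(pred)
  trends$group <- label_of(trends)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$n_initial,
                                     y = .data$proportion,
                                     colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.4,
                        position = ggplot2::position_jitter(width = 0.3,
                                                            height = 0)) +
    ggplot2::geom_line(data = trends, linewidth = 0.8) +
    ggplot2::labs(x = "Initial prey density", y = "Proportion killed",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
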