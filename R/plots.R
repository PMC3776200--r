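# ggplot2 views of the result objects

#' @export
autoplot.payoff_table <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(
      strategy = factor(.data$strategy, levels = rev(rownames(object$payoff))),
      opponent = factor(.data$opponent, levels = colnames(object$payoff))
    ) |>
    ggplot2::ggplot(ggplot2::aes(.data$opponent, .data$strategy,
                                 fill = .data$payoff)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3g", .data$payoff)), size = 3) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "opponent", y = "strategy",
                  fill = "payoff",
                  title = "Expected pairwise payoffs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.small_mutation_chain <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(strategy = factor(.data$strategy,
                                    levels = object$strategies)) |>
    ggplot2::ggplot(ggplot2::aes(.data$strategy, .data$stationary)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "stationary frequency",
                  title = sprintf("Small-mutation limit (N = %d, beta = %g)",
                                  object$N, object$beta)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.imitation_sim <- function(object, ...) {
  object$trajectory |>
    tidyr::pivot_longer(-"event", names_to = "strategy",
                        values_to = "count") |>
    dplyr::mutate(frequency = .data$count / object$config$N) |>
    ggplot2::ggplot(ggplot2::aes(.data$event, .data$frequency,
                                 colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "update event", y = "frequency",
                  title = "Agent-based imitation dynamics") +
    ggplot2::theme_minimal()
}

#' Plot stationary frequencies along an arrangement-cost sweep
#'
#' Line plot of each strategy's stationary frequency against the
#' arrangement cost, faceted by compensation level when the sweep covers
#' several.
#'
#' @param sweep A tibble from [sweep_stationary()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  p <- ggplot2::ggplot(sweep,
                       ggplot2::aes(.data$epsilon, .data$frequency,
                                    colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "arrangement cost", y = "stationary frequency") +
    ggplot2::theme_minimal()
  if (length(unique(sweep$delta)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$delta),
                                 labeller = ggplot2::label_both)
  }
  p
}
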