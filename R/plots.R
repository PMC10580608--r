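#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: the positive
#' level-error percentage per CHC domain for an error table, the per-cycle
#' loss trajectory for a trained surrogate, and expert vs predicted mean
#' levels for a comparison. `plot_transfer_matrix()` draws the transfer
#' weights as a heat map.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name chclevels-plots
NULL

#' @rdname chclevels-plots
#' @method autoplot chc_error_table
#' @export
autoplot.chc_error_table <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object),
    domain = factor(toupper(.data$domain), levels = toupper(chc_domains()))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$domain, y = .data$pct_gt0)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = "CHC domain", y = "Level error > 0 (%)",
      title = "Predictions above the expert level"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname chclevels-plots
#' @method autoplot chc_mlp
#' @export
autoplot.chc_mlp <- function(object, ...) {
  if (is.null(object$trajectory)) {
    abort("This fit has no stored loss trajectory.",
      class = "chclevels_validation_error"
    )
  }
  d <- tidyr::pivot_longer(object$trajectory, c("loss", "error"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(
      data = tibble(
        metric = "error", value = object$config$threshold %||% NA_real_
      ),
      ggplot2::aes(yintercept = .data$value), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "Cycle (epoch)", y = NULL,
      title = "Surrogate training trajectory"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname chclevels-plots
#' @method autoplot chc_comparison
#' @export
autoplot.chc_comparison <- function(object, ...) {
  d <- object$stat_report |>
    dplyr::select("domain", expert = "expert_mean", predicted = "predicted_mean") |>
    tidyr::pivot_longer(c("expert", "predicted"),
      names_to = "source", values_to = "mean_level"
    ) |>
    dplyr::mutate(
      domain = factor(toupper(.data$domain), levels = toupper(chc_domains()))
    )
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$domain, y = .data$mean_level, fill = .data$source)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "CHC domain", y = "Mean game level", fill = NULL,
      title = "Expert vs predicted mean levels"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname chclevels-plots
#' @param matrix A [transfer_matrix()].
#' @export
plot_transfer_matrix <- function(matrix = default_transfer_matrix()) {
  d <- as_tibble(unclass(matrix), rownames = "acer") |>
    tidyr::pivot_longer(-"acer", names_to = "chc", values_to = "weight") |>
    dplyr::filter(.data$weight > 0) |>
    dplyr::mutate(
      acer = factor(.data$acer, levels = rev(acer_domains())),
      chc = factor(toupper(.data$chc), levels = toupper(chc_domains()))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chc, y = .data$acer, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$weight, "%"))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "CHC domain", y = "ACE-R domain", fill = "%",
      title = "ACE-R to CHC transfer weights"
    ) +
    ggplot2::theme_minimal()
}
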