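#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a model report
#'
#' @param x A `regiosel_report`.
#' @param ... Unused.
#' @return The held-out predictions tibble (`row`, `arene_id`, `observed`,
#'   `predicted`) with a `residual` column.
#' @export
tidy.regiosel_report <- function(x, ...) {
  dplyr::mutate(x$predictions, residual = .data$observed - .data$predicted)
}

#' One-row summary of a model report
#'
#' @param x A `regiosel_report`.
#' @param ... Unused.
#' @return Tibble: `algorithm`, `mode`, `pearson_r`, `mae`, `n_pairs`,
#'   `n_features`, `seed`, `config_hash`.
#' @export
glance.regiosel_report <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, mode = x$mode,
                 pearson_r = x$pearson_r, mae = x$mae, n_pairs = x$n,
                 n_features = length(x$features), seed = x$seed,
                 config_hash = x$config_hash)
}

#' Ranking table of an algorithm comparison
#'
#' @param x A `regiosel_comparison` from [compare_algorithms()].
#' @param ... Unused.
#' @return Tibble with one row per algorithm, ranked by Pearson R (ties by
#'   MAE).
#' @export
glance.regiosel_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' @export
print.regiosel_report <- function(x, ...) {
  cat("<regiosel_report> ", x$algorithm, " (", x$mode, ")\n",
      "  Pearson R = ", formatC(x$pearson_r, digits = 3, format = "f"),
      ", MAE = ", formatC(x$mae, digits = 3, format = "f"),
      " kcal/mol over ", x$n, " held-out pairs\n",
      "  ", length(x$features), " features, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.regiosel_comparison <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' Observed-versus-predicted plot for a model report
#'
#' @param object A `regiosel_report`.
#' @param ... Unused.
#' @return A ggplot: held-out predictions against observations with the
#'   identity line.
#' @export
autoplot.regiosel_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = expression(paste("observed ", Delta * Delta * G, " (kcal/mol)")),
      y = expression(paste("predicted ", Delta * Delta * G, " (kcal/mol)")),
      title = sprintf("%s: R = %.3f, MAE = %.3f kcal/mol",
                      object$algorithm, object$pearson_r, object$mae)) +
    ggplot2::theme_minimal()
}

#' Algorithm-ranking plot for a comparison
#'
#' @param object A `regiosel_comparison`.
#' @param ... Unused.
#' @return A ggplot bar chart of leave-one-out Pearson R per algorithm,
#'   shaded by regression quality.
#' @export
autoplot.regiosel_comparison <- function(object, ...) {
  d <- glance(object)
  d$algorithm <- stats::reorder(d$algorithm, d$pearson_r)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$algorithm, y = .data$pearson_r,
                                  fill = .data$pearson_r)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_gradient(low = "#d0d8e8", high = "#2b4c7e",
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "leave-one-out Pearson R") +
    ggplot2::theme_minimal()
}

#' Feature-selection trajectory plot
#'
#' @param selection Result of [greedy_feature_selection()].
#' @return A ggplot of leave-one-out Pearson R against subset size.
#' @export
plot_selection_trajectory <- function(selection) {
  d <- selection$trajectory
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$pearson_r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$step, labels = d$feature) +
    ggplot2::labs(x = NULL, y = "leave-one-out Pearson R") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
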