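#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot fit statistics across class counts
#'
#' Line plot of the four information criteria against the number of
#' classes, with the automatically selected model marked. Lower is better
#' for every criterion.
#'
#' @param object An [scan_lca()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lca_scan
#' @export
autoplot.lca_scan <- function(object, ...) {
  df <- object$statistics |>
    dplyr::select("k", "bic", "sabic", "aic", "caic") |>
    tidyr::pivot_longer(-"k", names_to = "criterion",
                        values_to = "value") |>
    dplyr::mutate(criterion = toupper(.data$criterion))
  sel <- dplyr::filter(df, .data$k == object$selected_k,
                       .data$criterion == toupper(object$criterion))
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$value,
                                   colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_point(data = sel, shape = 1, size = 4,
                        colour = "black") +
    ggplot2::scale_x_continuous(breaks = object$statistics$k) +
    ggplot2::labs(x = "Number of classes (K)", y = "Criterion value",
                  colour = NULL,
                  title = "Latent class model fit statistics",
                  subtitle = sprintf("Circled: smallest %s (K = %s)",
                                     toupper(object$criterion),
                                     format(object$selected_k))) +
    ggplot2::theme_minimal()
}

#' Heatmap of conditional item probabilities
#'
#' Tile plot of the estimated item probabilities by class, restricted to
#' items that reach `threshold` in at least one class (the profile-defining
#' items); thresholded cells are outlined.
#'
#' @param object An [fit_lca()] object.
#' @param threshold Labeling threshold (default 0.30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lca_fit
#' @export
autoplot.lca_fit <- function(object, threshold = 0.30, ...) {
  df <- tidy(object)
  keep <- df |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(mx = max(.data$probability), .groups = "drop") |>
    dplyr::filter(.data$mx >= threshold)
  df <- dplyr::filter(df, .data$item %in% keep$item) |>
    dplyr::mutate(item = factor(.data$item, levels = rev(sort(keep$item))),
                  defining = .data$probability >= threshold)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$class), .data$item,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$defining),
                       fill = NA, colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Class", y = "Injury indicator (Barell cell)",
                  fill = "P(item | class)",
                  title = "Conditional item probabilities",
                  subtitle = sprintf(
                    "Outlined: probability >= %.2f (profile-defining)",
                    threshold)) +
    ggplot2::theme_minimal()
}

#' Bar chart of profile prevalences
#'
#' @param fit An [fit_lca()] object.
#' @return A ggplot object.
#' @export
plot_profile_prevalence <- function(fit) {
  prev <- tabulate(fit$assignment, nbins = fit$k) / fit$n
  df <- tibble::tibble(class = factor(seq_len(fit$k)), prevalence = prev)
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$prevalence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$prevalence)), vjust = -0.4,
      size = 3) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                expand = ggplot2::expansion(mult = c(0, 0.1))) +
    ggplot2::labs(x = "Injury profile (class)", y = "Share of cohort",
                  title = "Profile prevalence (maximum-probability assignment)") +
    ggplot2::theme_minimal()
}
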