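#' Plot a transfer classification
#'
#' Stacked vertical/horizontal percentage bars per generation, faceted by
#' context when several contexts are bound together.
#'
#' @param object A `tt_transfer` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tt_transfer <- function(object, ...) {
  df <- as_tibble(object) |>
    select(all_of(c("generation", "compartment", "cultivar",
                    "vertical_pct", "horizontal_pct"))) |>
    tidyr::pivot_longer(c("vertical_pct", "horizontal_pct"),
                        names_to = "origin", values_to = "pct") |>
    mutate(origin = ifelse(.data$origin == "vertical_pct", "vertical", "horizontal"),
           generation = factor(.data$generation, levels = tt_generation_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$pct, fill = .data$origin)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(compartment ~ cultivar) +
    ggplot2::labs(y = "% of taxa present in generation", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot stage-wise retention flows
#'
#' Retained set sizes per stage with the stage percentages annotated — the
#' numeric skeleton of a Sankey diagram.
#'
#' @param object A `tt_flow` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tt_flow <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- paste0(df$n_retained, "/", df$n_entering,
                     " (", df$stage_pct_rounded, "%)")
  ctx <- intersect(c("compartment", "cultivar"), names(df))
  df$context <- if (length(ctx) > 0) do.call(paste, c(df[ctx], sep = " / ")) else "flow"
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$stage), y = .data$n_retained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(~context, scales = "free_y") +
    ggplot2::labs(x = "transition stage", y = "taxa retained") +
    ggplot2::theme_minimal()
}

#' Plot a heritability screen
#'
#' Observed H2 per taxon, ordered, colored by permutation significance.
#'
#' @param object A `tt_heritability` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tt_heritability <- function(object, ...) {
  df <- as_tibble(object) |> arrange(.data$h2)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$h2,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "taxon rank", y = expression(H^2),
                  colour = "adjusted p < 0.05") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot alpha diversity by generation
#'
#' @param alpha The tibble from the pipeline's diversity stage (alpha metrics
#'   joined to metadata).
#' @param metric Which metric column to plot.
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha, metric = "shannon") {
  ggplot2::ggplot(alpha, ggplot2::aes(x = .data$generation, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_grid(compartment ~ cultivar) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
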