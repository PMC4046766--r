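# ggplot2 visualisations of profiles, models and results.

#' @describeIn build_profiles Coverage/read-start profile around a window.
#' @param object An `srna_profiles` object.
#' @method autoplot srna_profiles
#' @export
autoplot.srna_profiles <- function(object, from = 1L,
                                   to = object$genome_length, ...) {
  df <- tidy(object, from = from, to = to) |>
    tidyr::pivot_longer(c("read_starts", "coverage"),
                        names_to = "signal", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_step() +
    ggplot2::facet_grid(signal + strand ~ ., scales = "free_y") +
    ggplot2::labs(x = "genomic position (nt)", y = "reads",
                  title = paste0("library ", object$library, " profiles"))
}

#' @describeIn train_promoter_model Per-column base probabilities of the
#'   model matrices.
#' @param object A `promoter_model`.
#' @method autoplot promoter_model
#' @export
autoplot.promoter_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$prob, fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~matrix, scales = "free_x") +
    ggplot2::labs(x = "box position", y = "probability",
                  title = paste(object$sigma, "promoter model"))
}

#' Bar chart of functional-class enrichment
#'
#' @param enrichment [compute_enrichment()] output.
#' @param under_pct,over_pct Reference lines for the representation bounds.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, under_pct = 10, over_pct = 20) {
  df <- enrichment[!is.na(enrichment$class), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$fraction,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(under_pct, over_pct),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "functional class", y = "% genes with asRNA",
                  fill = NULL)
}

#' Box plot of transcript lengths per positional class
#'
#' @param regions Classified region tibble.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(regions) {
  ggplot2::ggplot(regions, ggplot2::aes(x = .data$class, y = .data$length)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "transcript length (nt)")
}
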