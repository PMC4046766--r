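#' Functional-class enrichment of asRNA targets
#'
#' For each functional gene class (eggNOG-style single-letter categories),
#' computes the fraction of member genes carrying at least one antisense RNA
#' and labels classes with more than `over_pct` percent targeted as
#' overrepresented and fewer than `under_pct` percent as underrepresented.
#' Genes with several asRNAs count once — the denominator logic is
#' gene-level. No significance test is applied by default (the rule is a
#' fixed cut-off, not a statistic); `binom_test = TRUE` adds a two-sided
#' binomial test of each class against the overall targeted fraction.
#'
#' @param asrna_target_genes Character vector of locus tags carrying at least
#'   one asRNA (duplicates allowed, counted once).
#' @param class_map Tibble with columns `gene`, `class` (one class per gene;
#'   `NA` class = unclassified).
#' @param under_pct,over_pct Percentage cut-offs for the labels.
#' @param binom_test Add a two-sided binomial test per class.
#' @return Tibble per class: `class`, `genes_total`, `genes_with_asrna`,
#'   `fraction` (percent), `label`; unclassified genes in a trailing `NA`
#'   row. The overall expected fraction (percent of all mapped genes
#'   targeted) is in the `expected_fraction` attribute.
#' @export
compute_enrichment <- function(asrna_target_genes, class_map,
                               under_pct = 10, over_pct = 20,
                               binom_test = FALSE) {
  stopifnot(all(c("gene", "class") %in% names(class_map)))
  if (anyDuplicated(class_map$gene)) {
    stop("class_map must assign at most one class per gene", call. = FALSE)
  }
  targets <- unique(asrna_target_genes)
  unknown <- setdiff(targets, class_map$gene)
  if (length(unknown) > 0) {
    warning(length(unknown), " asRNA target gene(s) absent from the class ",
            "map; excluded: ", paste(head(unknown, 5), collapse = ", "))
    targets <- setdiff(targets, unknown)
  }
  overall <- 100 * length(targets) / nrow(class_map)
  out <- class_map |>
    mutate(targeted = .data$gene %in% targets) |>
    group_by(class = .data$class) |>
    summarise(genes_total = dplyr::n(),
              genes_with_asrna = sum(.data$targeted),
              .groups = "drop") |>
    mutate(
      fraction = 100 * .data$genes_with_asrna / .data$genes_total,
      label = case_when(
        .data$fraction < under_pct ~ "under",
        .data$fraction > over_pct ~ "over",
        TRUE ~ "normal"
      )
    ) |>
    arrange(is.na(.data$class), .data$class)
  if (binom_test) {
    out$p_value <- purrr::map2_dbl(
      out$genes_with_asrna, out$genes_total,
      ~ stats::binom.test(.x, .y, p = overall / 100)$p.value
    )
  }
  attr(out, "expected_fraction") <- overall
  out
}
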