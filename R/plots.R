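#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cohort summary
#'
#' Stacked per-family phenotype composition with the segregating-variant
#' count overlaid as text, the visual analogue of the cohort overview table.
#'
#' @param object A `famseg_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot famseg_cohort_summary
#' @export
autoplot.famseg_cohort_summary <- function(object, ...) {
  long <- object$per_family |>
    tidyr::pivot_longer(
      c("n_affected", "n_suggestive", "n_unaffected"),
      names_to = "phenotype", values_to = "n"
    ) |>
    mutate(phenotype = sub("^n_", "", .data$phenotype))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$family_id, y = .data$n, fill = .data$phenotype
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = object$per_family,
      ggplot2::aes(
        x = .data$family_id,
        y = .data$n_affected + .data$n_suggestive + .data$n_unaffected + 0.3,
        label = .data$n_segregating
      ),
      inherit.aes = FALSE, size = 3, vjust = 0
    ) +
    ggplot2::scale_fill_manual(values = c(
      affected = "#b2182b", suggestive = "#fdae61", unaffected = "#74add1"
    )) +
    ggplot2::labs(
      x = "family", y = "genotyped members",
      fill = NULL,
      title = "Family composition and segregating-variant counts",
      subtitle = "number above each bar: variants segregating in that family"
    ) +
    ggplot2::theme_minimal()
}

#' Plot burden-test results
#'
#' Per-gene permutation p-values on a -log10 scale with a nominal 0.05
#' reference line.
#'
#' @param object A `famseg_burden` scan result.
#' @param alpha Reference level (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot famseg_burden
#' @export
autoplot.famseg_burden <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) |> arrange(.data$p_value)
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_value), y = .data$gene
  )) +
    ggplot2::geom_point(ggplot2::aes(size = .data$observed_statistic)) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(
      x = expression(-log[10](italic(p))), y = NULL,
      size = "observed\nstatistic",
      title = "Pedigree gene-burden permutation test"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-family segregating-variant counts
#'
#' @param results Long segregation tibble from [segregating_variants()].
#' @return A ggplot.
#' @export
plot_segregation_counts <- function(results) {
  df <- results |>
    group_by(.data$family_id) |>
    summarise(n = n_distinct(.data$variant_id), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family_id, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "family", y = "segregating variants",
      title = "Variants segregating with affection status, per family"
    ) +
    ggplot2::theme_minimal()
}
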