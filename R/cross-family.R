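#' Variants segregating in two or more families
#'
#' Aggregates per-family segregation results into one report row per variant
#' whose family set has size at least `min_families`. If the input carries a
#' `carrier_hom` column, any homozygous carriage in a contributing family is
#' surfaced as a zygosity note (`any_homozygous`).
#'
#' @param results Long segregation tibble (columns `family_id`, `variant_id`,
#'   optionally `gene`, `carrier_hom`; extra columns are carried through from
#'   the first contributing row).
#' @param min_families Minimum number of families (default 2).
#' @return A tibble, one row per shared variant: `variant_id`, `gene`,
#'   `families` (list-column, sorted), `n_families`, `any_homozygous`.
#' @export
shared_variants <- function(results, min_families = 2) {
  if (!"carrier_hom" %in% names(results)) results$carrier_hom <- FALSE
  if (!"gene" %in% names(results)) results$gene <- NA_character_
  results |>
    group_by(.data$variant_id) |>
    summarise(
      gene = first(.data$gene),
      families = list(sort(unique(.data$family_id))),
      n_families = n_distinct(.data$family_id),
      any_homozygous = any(.data$carrier_hom, na.rm = TRUE),
      .groups = "drop"
    ) |>
    filter(.data$n_families >= min_families) |>
    arrange(.data$variant_id)
}

#' Genes with multiple segregating variants across families
#'
#' A gene qualifies when it carries at least two distinct segregating
#' variants and the union of their contributing families spans at least two
#' families. This reading admits a gene with two same-family variants plus a
#' third in another family; the stricter interpretation — every variant
#' itself segregating in two or more families — is available via
#' `strict = TRUE`.
#'
#' Within-family multi-hit genes (two or more segregating variants inside a
#' single family) are a separate observation, reported by
#' [within_family_multihit()].
#'
#' @param results Long segregation tibble (needs `family_id`, `variant_id`,
#'   `gene`).
#' @param strict Require each variant to segregate in two or more families.
#' @return A tibble, one row per qualifying gene: `gene`, `n_variants`,
#'   `variant_ids` (list-column), `families` (list-column, sorted union),
#'   `n_families`.
#' @export
multi_variant_genes <- function(results, strict = FALSE) {
  results <- filter(results, !is.na(.data$gene))
  if (strict) {
    fam_per_variant <- results |>
      group_by(.data$variant_id) |>
      summarise(nf = n_distinct(.data$family_id), .groups = "drop")
    keep <- fam_per_variant$variant_id[fam_per_variant$nf >= 2]
    results <- filter(results, .data$variant_id %in% keep)
  }
  results |>
    group_by(.data$gene) |>
    summarise(
      n_variants = n_distinct(.data$variant_id),
      variant_ids = list(sort(unique(.data$variant_id))),
      families = list(sort(unique(.data$family_id))),
      n_families = n_distinct(.data$family_id),
      .groups = "drop"
    ) |>
    filter(.data$n_variants >= 2, .data$n_families >= 2) |>
    arrange(.data$gene)
}

#' Genes hit by multiple segregating variants inside one family
#'
#' @param results Long segregation tibble.
#' @return A tibble: `family_id`, `gene`, `n_variants`, `variant_ids`
#'   (list-column).
#' @export
within_family_multihit <- function(results) {
  results |>
    filter(!is.na(.data$gene)) |>
    group_by(.data$family_id, .data$gene) |>
    summarise(
      n_variants = n_distinct(.data$variant_id),
      variant_ids = list(sort(unique(.data$variant_id))),
      .groups = "drop"
    ) |>
    filter(.data$n_variants >= 2) |>
    arrange(.data$family_id, .data$gene)
}

#' Cohort-level summary of a family segregation analysis
#'
#' Per-family phenotype and segregating-variant counts plus cohort totals.
#' The mean segregating count is reported both exactly and rounded to the
#' nearest integer, so headline figures are reproducible without hiding
#' precision.
#'
#' @param counts Per-family counts: `family_id`, `n_affected`,
#'   `n_suggestive`, `n_unaffected`, `n_segregating` (see [family_counts()],
#'   or a transcribed overview table).
#' @return An object of class `famseg_cohort_summary`: a list with
#'   `per_family` (the input tibble) and scalar summaries (`n_families`,
#'   `n_individuals`, `total_affected`, `total_suggestive`,
#'   `total_unaffected`, `mean_segregating`, `mean_segregating_rounded`,
#'   `min_segregating`, `max_segregating`).
#' @export
cohort_summary <- function(counts) {
  if (nrow(counts) == 0) abort_domain("cohort_summary needs at least one family")
  structure(
    list(
      per_family = counts,
      n_families = nrow(counts),
      n_individuals = sum(counts$n_affected + counts$n_suggestive + counts$n_unaffected),
      total_affected = sum(counts$n_affected),
      total_suggestive = sum(counts$n_suggestive),
      total_unaffected = sum(counts$n_unaffected),
      mean_segregating = mean(counts$n_segregating),
      mean_segregating_rounded = as.integer(round(mean(counts$n_segregating))),
      min_segregating = min(counts$n_segregating),
      max_segregating = max(counts$n_segregating)
    ),
    class = "famseg_cohort_summary"
  )
}

#' @export
print.famseg_cohort_summary <- function(x, ...) {
  cat(sprintf(
    "Family cohort: %d families, %d individuals (%d affected / %d suggestive / %d unaffected)\n",
    x$n_families, x$n_individuals, x$total_affected, x$total_suggestive, x$total_unaffected
  ))
  cat(sprintf(
    "Segregating variants per family: mean %.2f (rounded %d), range %d-%d\n",
    x$mean_segregating, x$mean_segregating_rounded, x$min_segregating, x$max_segregating
  ))
  invisible(x)
}

#' Allelic odds ratio for a 2x2 allele-count table
#'
#' Cross-product odds ratio with a 95% confidence interval from the normal
#' approximation on the log scale and a two-sided Fisher exact p-value. When
#' any cell is zero, a +0.5 continuity correction (Haldane-Anscombe) is
#' applied to the odds ratio and interval — the p-value is always computed on
#' the uncorrected counts — and the result is flagged.
#'
#' @param case_alt,case_ref Alt and ref allele counts among cases.
#' @param ctrl_alt,ctrl_ref Alt and ref allele counts among controls.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `famseg_assoc`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `counts` (the 2x2 matrix), `corrected`.
#' @export
#' @examples
#' allelic_odds_ratio(10, 90, 5, 195)
allelic_odds_ratio <- function(case_alt, case_ref, ctrl_alt, ctrl_ref,
                               conf_level = 0.95) {
  counts <- matrix(
    c(case_alt, case_ref, ctrl_alt, ctrl_ref),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("case", "control"), c("alt", "ref"))
  )
  if (any(counts < 0)) abort_domain("allele counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort_domain("a margin of the 2x2 table is zero")
  }
  corrected <- any(counts == 0)
  w <- counts + if (corrected) 0.5 else 0
  or <- (w["case", "alt"] * w["control", "ref"]) /
    (w["case", "ref"] * w["control", "alt"])
  se <- sqrt(sum(1 / w))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- fisher.test(counts)$p.value
  structure(
    list(
      odds_ratio = unname(or),
      ci_low = unname(exp(log(or) - z * se)),
      ci_high = unname(exp(log(or) + z * se)),
      p_value = p,
      counts = counts,
      corrected = corrected
    ),
    class = "famseg_assoc"
  )
}

#' @export
print.famseg_assoc <- function(x, ...) {
  cat(sprintf(
    "Allelic odds ratio %.2f (95%% CI %.2f-%.2f), Fisher exact p = %.3g%s\n",
    x$odds_ratio, x$ci_low, x$ci_high, x$p_value,
    if (x$corrected) " [+0.5 continuity correction]" else ""
  ))
  invisible(x)
}
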