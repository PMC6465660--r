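#' Bundled reference tables
#'
#' Three small transcribed reference tables from a published multiplex-family
#' cohort analysis ship with the package so the cross-family aggregation
#' operations can be exercised against known headline figures: a per-family
#' overview (18 families, phenotype tallies, segregating-variant counts), the
#' variants that segregated in two families, and the genes with multiple
#' segregating variants across families.
#'
#' @param file One of `"family_overview.tsv"`,
#'   `"shared_variants_two_families.tsv"`, `"multi_variant_genes.tsv"`; with
#'   no argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
famseg_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "famseg")))
  }
  path <- system.file("extdata", file, package = "famseg")
  if (!nzchar(path)) abort_config(sprintf("no bundled file '%s'", file))
  path
}

read_fixture <- function(file) {
  readr::read_tsv(famseg_example(file),
    comment = "#", show_col_types = FALSE, progress = FALSE,
    na = c("", "NA")
  )
}

#' @describeIn famseg_example Per-family overview in the shape consumed by
#'   [cohort_summary()] (`family_id` coerced to character).
#' @export
load_family_overview <- function() {
  read_fixture("family_overview.tsv") |>
    mutate(family_id = as.character(.data$family_id))
}

#' @describeIn famseg_example Long (family x variant) table of variants
#'   segregating in two families, with `variant_id` and `carrier_hom` columns
#'   ready for [shared_variants()].
#' @export
load_shared_variant_table <- function() {
  read_fixture("shared_variants_two_families.tsv") |>
    mutate(
      family_id = as.character(.data$family_id),
      chrom = as.character(.data$chrom),
      variant_id = paste(.data$chrom, .data$pos, sep = ":"),
      carrier_hom = .data$homozygous_carrier
    )
}

#' @describeIn famseg_example Long (family x variant) table of gene-level
#'   multi-variant evidence, with `variant_id`, ready for
#'   [multi_variant_genes()].
#' @export
load_gene_table <- function() {
  read_fixture("multi_variant_genes.tsv") |>
    mutate(
      family_id = as.character(.data$family_id),
      chrom = as.character(.data$chrom),
      variant_id = paste(.data$chrom, .data$pos, sep = ":")
    )
}
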