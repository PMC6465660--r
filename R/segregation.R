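#' Remove variants carried by any unaffected individual
#'
#' Global (cross-family) removal under an assumption of complete penetrance:
#' any variant with an alt count of at least 1 in any genotyped, non-exempt
#' unaffected individual — in any family — is removed. Individuals with the
#' suggestive phenotype or an unknown phenotype never trigger removal, and
#' penetrance-exempt unaffected individuals are skipped (reduced penetrance
#' in their family makes their non-affection uninformative). Missing
#' genotypes do not count as carriage.
#'
#' @param variants Variant tibble.
#' @param ped Pedigree tibble (after [align_samples()]).
#' @return The retained variant tibble; removed variant ids in attribute
#'   `"removed"`.
#' @export
remove_global_unaffected_carriers <- function(variants, ped) {
  blockers <- ped$individual_id[
    ped$genotyped & ped$phenotype == "unaffected" & !ped$penetrance_exempt
  ]
  carried <- map_lgl(variants$geno, function(g) {
    g <- g[intersect(blockers, names(g))]
    any(!is.na(g) & g >= 1L)
  })
  out <- variants[!carried, , drop = FALSE]
  attr(out, "samples") <- attr(variants, "samples")
  attr(out, "removed") <- variants$variant_id[carried]
  out
}

#' Classify one variant's segregation in one family
#'
#' A variant *segregates* when every genotyped affected member carries at
#' least one alt allele (heterozygous and homozygous both count as carriage)
#' and no genotyped non-exempt unaffected member carries any; it is
#' *incomplete* when all affected carry but at least one unaffected does; it
#' *fails* otherwise. A missing genotype in an affected member fails the
#' "present in all affected" requirement (conservative); in an unaffected
#' member it does not count as carriage. Suggestive individuals are ignored
#' in both directions.
#'
#' @param fam_ped Pedigree rows of a single family.
#' @param geno Named integer alt counts for one variant.
#' @return One of `"segregates"`, `"incomplete"`, `"fails"`.
#' @export
classify_segregation <- function(fam_ped, geno) {
  aff <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "affected"]
  if (length(aff) == 0) {
    abort(
      sprintf("family '%s' has no genotyped affected member", fam_ped$family_id[1]),
      class = "famseg_not_evaluable_error"
    )
  }
  una <- fam_ped$individual_id[
    fam_ped$genotyped & fam_ped$phenotype == "unaffected" & !fam_ped$penetrance_exempt
  ]
  g_aff <- geno[intersect(aff, names(geno))]
  all_aff_carry <- length(g_aff) == length(aff) && all(!is.na(g_aff) & g_aff >= 1L)
  if (!all_aff_carry) return("fails")
  g_una <- geno[intersect(una, names(geno))]
  if (any(!is.na(g_una) & g_una >= 1L)) "incomplete" else "segregates"
}

#' Per-family segregating variants
#'
#' Evaluates [classify_segregation()] for every (family, variant) pair and
#' returns the fully segregating ones as a long tibble, ordered by
#' `(family_id, chrom, pos, alt)` (lexicographic on `chrom` and `alt`) for
#' reproducible diffs. Families without a genotyped affected member are
#' skipped. Homozygous carriage among affected members is flagged per row
#' (`carrier_hom`) for downstream zygosity notes.
#'
#' @param variants Variant tibble (normally after
#'   [remove_global_unaffected_carriers()]).
#' @param ped Pedigree tibble.
#' @return A tibble: `family_id`, `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `rsid`, `gene`, `cadd_phred`, `carrier_hom`.
#' @export
segregating_variants <- function(variants, ped) {
  fams <- unique(ped$family_id)
  rows <- map(fams, function(fam) {
    fam_ped <- ped[ped$family_id == fam, ]
    aff <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "affected"]
    if (length(aff) == 0) return(NULL)
    status <- map_chr(variants$geno, \(g) classify_segregation(fam_ped, g))
    hit <- status == "segregates"
    if (!any(hit)) return(NULL)
    hom <- map_lgl(variants$geno[hit], function(g) {
      g <- g[intersect(aff, names(g))]
      any(!is.na(g) & g == 2L)
    })
    sub <- variants[hit, intersect(
      c("variant_id", "chrom", "pos", "ref", "alt", "rsid", "gene", "cadd_phred"),
      names(variants)
    )]
    sub$carrier_hom <- hom
    sub$family_id <- fam
    sub
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      family_id = character(), variant_id = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(), rsid = character(),
      gene = character(), cadd_phred = double(), carrier_hom = logical()
    ))
  }
  out |>
    select("family_id", everything()) |>
    arrange(.data$family_id, .data$chrom, .data$pos, .data$alt)
}

#' Per-family segregation counts
#'
#' Builds the per-family overview (phenotype tallies of genotyped members
#' plus the number of segregating variants) in the shape consumed by
#' [cohort_summary()].
#'
#' @param results Long segregation tibble from [segregating_variants()].
#' @param ped Pedigree tibble.
#' @return A tibble: `family_id`, `n_affected`, `n_suggestive`,
#'   `n_unaffected`, `n_segregating`.
#' @export
family_counts <- function(results, ped) {
  pheno <- ped |>
    filter(.data$genotyped) |>
    group_by(.data$family_id) |>
    summarise(
      n_affected = sum(.data$phenotype == "affected"),
      n_suggestive = sum(.data$phenotype == "suggestive"),
      n_unaffected = sum(.data$phenotype == "unaffected"),
      .groups = "drop"
    )
  seg <- results |>
    group_by(.data$family_id) |>
    summarise(n_segregating = n_distinct(.data$variant_id), .groups = "drop")
  pheno |>
    left_join(seg, by = "family_id") |>
    mutate(n_segregating = ifelse(is.na(.data$n_segregating), 0L, .data$n_segregating))
}
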