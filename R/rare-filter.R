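#' Rare-variant filter configuration
#'
#' Bundles every tunable threshold of the variant-level filter cascade.
#' Defaults mirror a conventional dominant rare-variant exome workflow: a
#' variant is population-rare when every reference-panel frequency is missing,
#' at most 1%, or at least 99% (the flipped branch catches sites where the
#' panel's reference allele is the minor one), and when the in-cohort control
#' minor allele frequency is below 1%; protein-altering effect classes are
#' retained; a scaled CADD score of at least 20 (the 1% most deleterious
#' substitutions genome-wide) is required unless the variant is an indel with
#' no CADD annotation; and adult-onset actionable genes are removed to avoid
#' secondary findings.
#'
#' @param maf_threshold Population rarity threshold (default 0.01).
#' @param flipped_threshold Flipped-allele branch threshold (default 0.99);
#'   applies to reference-panel sources only, not `control_maf`, which is
#'   already folded to the minor allele.
#' @param control_maf_threshold In-cohort control threshold; variants with
#'   `control_maf >=` this are removed (default 0.01).
#' @param cadd_threshold Minimum CADD phred score (default 20, inclusive).
#' @param retained_effects Effect classes that survive the effect filter.
#' @param excluded_genes Genes removed regardless of other evidence.
#' @param af_sources Population sources consulted (as `af_<source>` columns).
#' @param hwe_threshold Carried alongside for pipeline use (see
#'   [qc_prefilter()]).
#' @return A list of class `famseg_filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          flipped_threshold = 0.99,
                          control_maf_threshold = 0.01,
                          cadd_threshold = 20,
                          retained_effects = c(
                            "frameshift_indel", "nonframeshift_indel",
                            "nonsynonymous", "stopgain", "stoploss",
                            "unknown_effect", "splicing"
                          ),
                          excluded_genes = acmg_adult_onset_genes,
                          af_sources = default_af_sources,
                          hwe_threshold = 1e-8) {
  if (!(maf_threshold > 0 && maf_threshold < flipped_threshold && flipped_threshold < 1)) {
    abort_config("thresholds must satisfy 0 < maf_threshold < flipped_threshold < 1")
  }
  bad <- setdiff(retained_effects, effect_classes)
  if (length(bad) > 0) abort_config(sprintf("unknown effect class '%s'", bad[1]))
  structure(
    list(
      maf_threshold = maf_threshold,
      flipped_threshold = flipped_threshold,
      control_maf_threshold = control_maf_threshold,
      cadd_threshold = cadd_threshold,
      retained_effects = retained_effects,
      excluded_genes = excluded_genes,
      af_sources = af_sources,
      hwe_threshold = hwe_threshold
    ),
    class = "famseg_filter_config"
  )
}

#' Population and control rarity test
#'
#' `TRUE` iff, for every configured population source, the frequency is
#' missing, at most `maf_threshold`, or at least `flipped_threshold`, *and*
#' the in-cohort control MAF is missing or strictly below
#' `control_maf_threshold`. A variant absent from every reference panel is
#' treated as rare: absence from panels of this size is itself strong
#' evidence of rarity (configurable by supplying frequencies).
#'
#' @param variants Variant tibble (rows are vectorised over).
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per row.
#' @export
is_population_rare <- function(variants, cfg = filter_config()) {
  ok <- rep(TRUE, nrow(variants))
  for (src in cfg$af_sources) {
    col <- paste0("af_", src)
    if (!col %in% names(variants)) next
    af <- variants[[col]]
    if (any(!is.na(af) & (af < 0 | af > 1))) {
      abort_domain(sprintf("frequency outside [0, 1] in column '%s'", col))
    }
    ok <- ok & (is.na(af) | af <= cfg$maf_threshold | af >= cfg$flipped_threshold)
  }
  ctrl <- variants$control_maf %||% rep(NA_real_, nrow(variants))
  if (any(!is.na(ctrl) & (ctrl < 0 | ctrl > 1))) {
    abort_domain("control_maf outside [0, 1]")
  }
  ok & (is.na(ctrl) | ctrl < cfg$control_maf_threshold)
}

#' Effect-class and CADD deleteriousness test
#'
#' `TRUE` iff the effect class is retained and the CADD phred score is at
#' least `cadd_threshold`, or missing for an indel (indels are frequently
#' unscored by CADD releases, so an unknown score does not disqualify them).
#' A missing effect class fails: a protein-altering consequence cannot be
#' confirmed for an unannotated variant.
#'
#' @inheritParams is_population_rare
#' @return Logical vector, one element per row.
#' @export
passes_effect_and_cadd <- function(variants, cfg = filter_config()) {
  eff_ok <- !is.na(variants$effect) & variants$effect %in% cfg$retained_effects
  cadd <- variants$cadd_phred
  is_indel <- variants$is_indel %||% (nchar(variants$ref) != nchar(variants$alt))
  cadd_ok <- (!is.na(cadd) & cadd >= cfg$cadd_threshold) | (is.na(cadd) & is_indel)
  eff_ok & cadd_ok
}

#' Apply the variant-level rare-variant filter cascade
#'
#' Rules are applied in cascade order — population rarity, in-cohort control
#' rarity, effect class, CADD, excluded-gene removal — and every input variant
#' receives exactly one decision recording the first rule it failed (or a
#' `retained` verdict). The retained set is independent of input order.
#'
#' @param variants Variant tibble that has passed [qc_prefilter()].
#' @param cfg A [filter_config()].
#' @return The retained variant tibble with attributes `"decisions"` (tibble
#'   `variant_id`, `verdict`, `failed_rule`) and `"tally"` (removals per
#'   rule).
#' @export
apply_rare_filters <- function(variants, cfg = filter_config()) {
  n <- nrow(variants)
  if (n == 0) {
    out <- variants
    attr(out, "decisions") <- tibble(
      variant_id = character(), verdict = character(), failed_rule = character()
    )
    attr(out, "tally") <- integer(0)
    return(out)
  }
  failed <- rep(NA_character_, n)

  pop_ok <- rep(TRUE, n)
  for (src in cfg$af_sources) {
    col <- paste0("af_", src)
    if (!col %in% names(variants)) next
    af <- variants[[col]]
    pop_ok <- pop_ok & (is.na(af) | af <= cfg$maf_threshold | af >= cfg$flipped_threshold)
  }
  failed[is.na(failed) & !pop_ok] <- "population_af"

  ctrl <- variants$control_maf %||% rep(NA_real_, n)
  ctrl_bad <- !is.na(ctrl) & ctrl >= cfg$control_maf_threshold
  failed[is.na(failed) & ctrl_bad] <- "control_maf"

  eff_ok <- !is.na(variants$effect) & variants$effect %in% cfg$retained_effects
  failed[is.na(failed) & !eff_ok] <- "effect_class"

  cadd <- variants$cadd_phred
  is_indel <- variants$is_indel %||% (nchar(variants$ref) != nchar(variants$alt))
  cadd_ok <- (!is.na(cadd) & cadd >= cfg$cadd_threshold) | (is.na(cadd) & is_indel)
  failed[is.na(failed) & !cadd_ok] <- "cadd"

  acmg <- !is.na(variants$gene) & variants$gene %in% cfg$excluded_genes
  failed[is.na(failed) & acmg] <- "acmg_gene"

  decisions <- tibble(
    variant_id = variants$variant_id,
    verdict = ifelse(is.na(failed), "retained", "removed"),
    failed_rule = failed
  )
  out <- variants[is.na(failed), , drop = FALSE]
  attr(out, "samples") <- attr(variants, "samples")
  attr(out, "decisions") <- decisions
  attr(out, "tally") <- table(failed)[c("population_af", "control_maf", "effect_class", "cadd", "acmg_gene")] |>
    (\(t) setNames(as.integer(ifelse(is.na(t), 0L, t)),
                   c("population_af", "control_maf", "effect_class", "cadd", "acmg_gene")))()
  out
}
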