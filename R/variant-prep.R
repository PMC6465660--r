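#' Decompose multiallelic sites into biallelic variant records
#'
#' One biallelic record is emitted per alt allele. Each sample's alt count for
#' record *k* is the number of allele-*k* copies in the original genotype, so
#' total non-reference allele copies are conserved across the decomposition.
#' Shared leading bases between ref and alt are trimmed first (advancing the
#' position), then shared trailing bases, always keeping at least one base of
#' each allele. No reference genome is consulted, so full left-alignment
#' against flanking sequence is not performed; prefix/suffix trimming is the
#' supported normalisation.
#'
#' @param sites Raw site tibble from [read_vcf()] (columns `chrom`, `pos`,
#'   `rsid`, `ref`, `alt` possibly comma-separated, `gt` list-column of GT
#'   strings).
#' @return A variant tibble with columns `chrom`, `pos`, `ref`, `alt`, `rsid`,
#'   `variant_id` and `geno` (named integer alt counts, `NA` = missing).
#'   Biallelic input rows pass through unchanged apart from trimming.
#' @export
decompose_multiallelic <- function(sites) {
  samples <- names(sites$gt[[1]])
  rows <- pmap(
    list(sites$chrom, sites$pos, sites$rsid, sites$ref, sites$alt, sites$gt,
         seq_len(nrow(sites))),
    function(chrom, pos, rsid, ref, alt, gt, i) {
      alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
      n_alt <- length(alts)
      idx <- map(gt, parse_gt, n_alt = n_alt, where = sprintf(" (record %d)", i))
      map(seq_len(n_alt), function(k) {
        counts <- map_int(idx, function(a) {
          if (is.null(a)) NA_integer_ else sum(a == k)
        })
        trimmed <- trim_alleles(pos, ref, alts[k])
        tibble(
          chrom = chrom, pos = trimmed$pos, ref = trimmed$ref, alt = trimmed$alt,
          rsid = rsid, geno = list(setNames(counts, samples))
        )
      })
    }
  )
  out <- bind_rows(unlist(rows, recursive = FALSE))
  out$variant_id <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  out[, c("chrom", "pos", "ref", "alt", "rsid", "variant_id", "geno")]
}

# Trim shared leading bases (advancing pos), then shared trailing bases,
# keeping at least one base of each allele.
trim_alleles <- function(pos, ref, alt) {
  if (ref == alt) abort_consistency(sprintf("ref equals alt ('%s') at pos %d", ref, pos))
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Genotype counts of a biallelic variant
#'
#' Missing genotypes are excluded, not imputed.
#'
#' @param geno Named integer vector of alt counts (0/1/2, `NA` missing).
#' @param samples Optional subset of sample ids to count over.
#' @return A list with `n_hom_ref`, `n_het`, `n_hom_alt`.
#' @export
genotype_counts <- function(geno, samples = NULL) {
  if (!is.null(samples)) geno <- geno[intersect(samples, names(geno))]
  geno <- geno[!is.na(geno)]
  list(
    n_hom_ref = sum(geno == 0L),
    n_het = sum(geno == 1L),
    n_hom_alt = sum(geno == 2L)
  )
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' follows a known exact distribution under Hardy-Weinberg equilibrium. The
#' p-value is the total probability of all heterozygote counts whose
#' probability does not exceed that of the observed count (a two-sided exact
#' test). Monomorphic sites return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total > 0).
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_p(10, 0, 0) # monomorphic: 1
#' hwe_exact_p(25, 50, 25) # equilibrium-looking: large p
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  if (n_hom_ref < 0 || n_het < 0 || n_hom_alt < 0) {
    abort_domain("genotype counts must be non-negative")
  }
  n <- n_hom_ref + n_het + n_hom_alt
  if (n <= 0) abort_domain("total genotype count must be positive")
  r <- 2 * min(n_hom_ref, n_hom_alt) + n_het # minor allele count
  if (r == 0) return(1)
  h <- seq.int(r %% 2, min(r, 2 * n - r), by = 2)
  logp <- lfactorial(n) - lfactorial((r - h) / 2) - lfactorial(h) -
    lfactorial(n - (r + h) / 2) + h * log(2) +
    lfactorial(r) + lfactorial(2 * n - r) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p_obs <- p[h == n_het]
  min(1, sum(p[p <= p_obs * (1 + 1e-10)]) / sum(p))
}

#' Dataset-level quality prefilter
#'
#' Applies, in order, the three dataset-level exclusions run after joint
#' calling and before rare-variant filtering:
#'
#' 1. `lcr` — position lies in a low-complexity (or otherwise excluded)
#'    region;
#' 2. `hwe` — exact Hardy-Weinberg p-value strictly below `hwe_threshold`
#'    (equality retains the variant), computed over `hwe_samples`;
#' 3. `mac` — zero minor-allele copies among `family_samples` (the variant
#'    does not vary in the families of interest).
#'
#' Each removed variant is tallied under the first rule it fails. The
#' Hardy-Weinberg sample set defaults to every genotyped sample in the joint
#' input; relatedness between family members biases this test and the sample
#' set is therefore configurable.
#'
#' @param variants Variant tibble (biallelic, from [parse_variant_table()]).
#' @param lcr Region tibble from [read_bed_regions()] (may be empty).
#' @param family_samples Sample ids of the family members.
#' @param hwe_threshold Exclusion threshold for the exact test (default
#'   `1e-8`).
#' @param hwe_samples Samples over which the HWE test is computed; defaults to
#'   all samples carried by the genotype vectors.
#' @return The retained variant tibble, with the per-rule removal tally as
#'   attribute `"tally"` (named integer: lcr, hwe, mac) and the per-variant
#'   removal reasons as attribute `"removed"` (tibble `variant_id`, `rule`).
#' @export
qc_prefilter <- function(variants, lcr, family_samples,
                         hwe_threshold = 1e-8, hwe_samples = NULL) {
  if (length(family_samples) == 0) abort_config("family_samples must be non-empty")
  n <- nrow(variants)
  reason <- rep(NA_character_, n)

  in_lcr <- if (nrow(lcr) > 0) in_regions(variants$chrom, variants$pos, lcr) else rep(FALSE, n)
  reason[in_lcr] <- "lcr"

  todo <- which(is.na(reason))
  hwe_p <- map_dbl(variants$geno[todo], function(g) {
    cnt <- genotype_counts(g, hwe_samples)
    total <- cnt$n_hom_ref + cnt$n_het + cnt$n_hom_alt
    if (total == 0) return(1) # untestable site: no evidence against HWE
    hwe_exact_p(cnt$n_hom_ref, cnt$n_het, cnt$n_hom_alt)
  })
  reason[todo[hwe_p < hwe_threshold]] <- "hwe"

  todo <- which(is.na(reason))
  mac <- map_int(variants$geno[todo], function(g) {
    g <- g[intersect(family_samples, names(g))]
    g <- g[!is.na(g)]
    alt_copies <- sum(g)
    as.integer(min(alt_copies, 2L * length(g) - alt_copies))
  })
  reason[todo[mac < 1L]] <- "mac"

  removed <- tibble(variant_id = variants$variant_id, rule = reason) |>
    filter(!is.na(.data$rule))
  out <- variants[is.na(reason), , drop = FALSE]
  attr(out, "samples") <- attr(variants, "samples")
  attr(out, "tally") <- c(
    lcr = sum(reason == "lcr", na.rm = TRUE),
    hwe = sum(reason == "hwe", na.rm = TRUE),
    mac = sum(reason == "mac", na.rm = TRUE)
  )
  attr(out, "removed") <- removed
  out
}
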