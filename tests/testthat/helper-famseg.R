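# Shared builders and independent oracles for the test suite.

# Nuclear family pedigree tibble: two founders plus children.
nuclear_ped <- function(fam = "FAM", n_children = 3,
                        founder_pheno = c("unknown", "unknown"),
                        child_pheno = rep("affected", n_children),
                        founder_genotyped = TRUE,
                        exempt = character()) {
  ids <- c("p1", "p2", paste0("c", seq_len(n_children)))
  tibble::tibble(
    family_id = fam,
    individual_id = ids,
    father_id = c(NA, NA, rep("p1", n_children)),
    mother_id = c(NA, NA, rep("p2", n_children)),
    sex = c("male", "female", rep("unknown", n_children)),
    phenotype = c(founder_pheno, child_pheno),
    penetrance_exempt = ids %in% exempt,
    genotyped = c(rep(founder_genotyped, 2), rep(TRUE, n_children))
  )
}

# Minimal variant tibble from named genotype vectors.
variant_tbl <- function(genos, genes = NULL, chrom = NULL, effect = "nonsynonymous",
                        cadd = 25, control_maf = 0.001) {
  n <- length(genos)
  chrom <- chrom %||% as.character(seq_len(n))
  tb <- tibble::tibble(
    chrom = chrom, pos = 1000L + seq_len(n),
    ref = "A", alt = "T",
    rsid = NA_character_,
    geno = lapply(genos, function(g) {
      storage.mode(g) <- "integer"
      g
    }),
    gene = genes %||% paste0("G", seq_len(n)),
    effect = effect, control_maf = control_maf, cadd_phred = cadd
  )
  for (src in famseg::default_af_sources) tb[[paste0("af_", src)]] <- 0.001
  tb$is_indel <- FALSE
  tb$variant_id <- paste(tb$chrom, tb$pos, tb$ref, tb$alt, sep = ":")
  tb
}

`%||%` <- rlang::`%||%`

# Independent HWE oracle: direct multinomial/hypergeometric formula via
# lchoose, no recurrence shared with the implementation.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  r <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (r == 0) return(1)
  h <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  # P(h) = choose(n; homA, het, homB) * 2^h / choose(2n, r)
  logp <- lchoose(n, (r - h) / 2) + lchoose(n - (r - h) / 2, h) +
    h * log(2) - lchoose(2 * n, r)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[h == n_het]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# Brute-force HWE oracle for tiny n: enumerate every placement of the minor
# alleles into 2n allele slots, pair consecutive slots into genotypes.
hwe_oracle_bruteforce <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  r <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (r == 0) return(1)
  slots <- utils::combn(2 * n, r)
  het_of <- apply(slots, 2, function(idx) {
    x <- integer(2 * n)
    x[idx] <- 1L
    pair_sum <- x[seq(1, 2 * n, 2)] + x[seq(2, 2 * n, 2)]
    sum(pair_sum == 1L)
  })
  tab <- table(het_of) / ncol(slots)
  obs <- tab[[as.character(n_het)]]
  min(1, sum(tab[tab <= obs * (1 + 1e-10)]))
}

# Independent allele-trimming oracle using substring comparison from the
# string ends (different mechanics from the character-vector implementation).
trim_oracle <- function(pos, ref, alt) {
  lead <- 0
  while (nchar(ref) - lead > 1 && nchar(alt) - lead > 1 &&
    substr(ref, lead + 1, lead + 1) == substr(alt, lead + 1, lead + 1)) {
    lead <- lead + 1
  }
  ref <- substr(ref, lead + 1, nchar(ref))
  alt <- substr(alt, lead + 1, nchar(alt))
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
    substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  list(pos = pos + lead, ref = ref, alt = alt)
}

# Two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b # row 1
  n <- c + d # row 2
  k <- a + c # col 1
  x <- max(0, k - n):min(k, m)
  p <- dhyper(x, m, n, k)
  sum(p[p <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Write a small VCF from a site table (chrom, pos, id, ref, alt, gt strings).
write_test_vcf <- function(path, samples, rows) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
      collapse = "\t"
    )
  )
  body <- vapply(rows, function(r) paste(r, collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

# One shared default synthetic cohort per test run (built lazily; several
# test files exercise it).
sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(sim_cache$sim)) {
    sim_cache$sim <- famseg::simulate_dataset(
      famseg::simulation_config(seed = 20260921),
      dir = file.path(tempdir(), "famseg-shared-sim")
    )
  }
  sim_cache$sim
}
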