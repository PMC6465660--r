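#' Specification of a planted variant
#'
#' Describes one variant the simulator plants with a known carrier pattern so
#' its pipeline fate is predictable: `fully_segregating` variants are carried
#' by every affected member of each target family and by no unaffected
#' member; `incomplete` variants are additionally carried by one non-exempt
#' unaffected member of the target family (and are therefore removed by the
#' unaffected-carrier rule); `null` variants are dropped through the
#' pedigrees independently of phenotype. All planted variants are
#' population-rare, protein-altering and CADD-qualifying by construction.
#'
#' @param target_families Family ids the variant is planted in.
#' @param gene Gene symbol.
#' @param effect Effect class (an indel effect class implies `indel`).
#' @param cadd CADD phred score (at least 20), or `NA` for an unscored indel.
#' @param mode One of `fully_segregating`, `incomplete`, `null`.
#' @param indel Emit the variant as a deletion rather than a SNV.
#' @param hom_family Optional family in which the first affected carrier is
#'   homozygous (exercises the zygosity note on shared-variant reports).
#' @param exempt_carrier Plant an alt allele in the designated
#'   penetrance-exempt unaffected member of each target family (the variant
#'   must still survive the unaffected-carrier rules).
#' @return A list of class `famseg_plant_spec`.
#' @export
plant_spec <- function(target_families, gene,
                       effect = "nonsynonymous", cadd = 25,
                       mode = c("fully_segregating", "incomplete", "null"),
                       indel = FALSE, hom_family = NULL, exempt_carrier = FALSE) {
  mode <- match.arg(mode)
  if (!effect %in% effect_classes) abort_config(sprintf("unknown effect '%s'", effect))
  if (!is.na(cadd) && cadd < 20) abort_config("planted variants must have CADD >= 20 (or NA for an indel)")
  if (is.na(cadd) && !indel) abort_config("missing CADD is only allowed for indels")
  structure(
    list(
      target_families = target_families, gene = gene, effect = effect,
      cadd = cadd, mode = mode, indel = indel, hom_family = hom_family,
      exempt_carrier = exempt_carrier
    ),
    class = "famseg_plant_spec"
  )
}

default_plant_specs <- function() {
  list(
    plant_spec(c("F01", "F02"), "PLNT1", cadd = 27.8, hom_family = "F01"),
    plant_spec("F07", "PLNT2", cadd = 24),
    plant_spec("F03", "PLNT3", cadd = 26, mode = "incomplete"),
    plant_spec("F14", "PLNT4", cadd = 23, exempt_carrier = TRUE),
    plant_spec("F05", "PLNT5", cadd = 22),
    plant_spec("F06", "PLNT5", cadd = 30),
    plant_spec(c("F08", "F09"), "PLNT6",
      effect = "frameshift_indel", cadd = NA, indel = TRUE
    )
  )
}

#' Synthetic cohort configuration
#'
#' The defaults emulate the study conditions of a multiplex-family exome
#' cohort: 18 families of 2-7 genotyped members over 2-3 generations, a
#' phenotype mix targeting 33 affected / 18 suggestive / 21 unaffected out of
#' 72, rare heterozygous background variants with a log-uniform minor allele
#' frequency spectrum transmitted through the pedigrees by Mendelian gene
#' dropping, planted variants with known segregation behaviour, and a set of
#' deliberate violators of every filter rule so each removal tally is
#' exercised.
#'
#' @param n_families Number of families.
#' @param family_size_range Genotyped members per family, `(min, max)`.
#' @param max_generations 2 or 3.
#' @param affected_fraction_target,suggestive_fraction Expected phenotype mix
#'   among genotyped members.
#' @param n_background_variants Background variant count.
#' @param background_maf_range Log-uniform MAF spectrum bounds.
#' @param planted_variants List of [plant_spec()]s.
#' @param penetrance Probability that a planted carrier in a target family
#'   expresses the affected phenotype (carriers failing the draw are recorded
#'   as unaffected and listed as exemption candidates in the truth table).
#' @param missing_genotype_rate Missingness applied to background genotypes
#'   (planted variants and rule violators stay fully observed so their truth
#'   fates are deterministic).
#' @param n_violators_per_rule Deliberate violators per filter rule.
#' @param n_multiallelic Multiallelic (two-alt) background sites, exercising
#'   decomposition.
#' @param seed Master seed.
#' @return A list of class `famseg_sim_config`.
#' @export
simulation_config <- function(n_families = 18,
                              family_size_range = c(2, 7),
                              max_generations = 3,
                              affected_fraction_target = 33 / 72,
                              suggestive_fraction = 18 / 72,
                              n_background_variants = 300,
                              background_maf_range = c(1e-4, 0.2),
                              planted_variants = default_plant_specs(),
                              penetrance = 1.0,
                              missing_genotype_rate = 0.02,
                              n_violators_per_rule = 3,
                              n_multiallelic = 2,
                              seed = 1) {
  if (family_size_range[1] < 2 || family_size_range[2] < family_size_range[1]) {
    abort_config("family_size_range must be ordered with a minimum of 2")
  }
  if (!max_generations %in% 2:4) abort_config("max_generations must be 2, 3 or 4")
  fr <- c(affected_fraction_target, suggestive_fraction, penetrance, missing_genotype_rate)
  if (any(fr < 0 | fr > 1) || affected_fraction_target + suggestive_fraction > 1) {
    abort_config("phenotype fractions and rates must lie in [0, 1]")
  }
  structure(
    list(
      n_families = n_families, family_size_range = family_size_range,
      max_generations = max_generations,
      affected_fraction_target = affected_fraction_target,
      suggestive_fraction = suggestive_fraction,
      n_background_variants = n_background_variants,
      background_maf_range = background_maf_range,
      planted_variants = planted_variants,
      penetrance = penetrance,
      missing_genotype_rate = missing_genotype_rate,
      n_violators_per_rule = n_violators_per_rule,
      n_multiallelic = n_multiallelic,
      seed = seed
    ),
    class = "famseg_sim_config"
  )
}

#' Simulate a multiplex-family pedigree cohort
#'
#' Builds acyclic 2-3 generation pedigrees with the configured genotyped
#' sizes, assigns three-state phenotypes to hit the target fractions in
#' expectation (always at least one affected genotyped member per family) and
#' occasionally includes an ungenotyped member, mirroring relatives who
#' declined sequencing. Deterministic for a fixed seed.
#'
#' @param cfg A [simulation_config()].
#' @return A pedigree tibble (see [read_pedigree()]).
#' @export
simulate_pedigrees <- function(cfg = simulation_config()) {
  with_seed(cfg$seed, sim_pedigrees_impl(cfg))
}

sim_pedigrees_impl <- function(cfg) {
  fams <- sprintf("F%02d", seq_len(cfg$n_families))
  rows <- map(fams, function(fam) {
    s <- sample(seq(cfg$family_size_range[1], cfg$family_size_range[2]), 1)
    three_gen <- cfg$max_generations >= 3 && s >= 5 && runif(1) < 0.5
    n_gf <- sample(0:min(2, s - 1), 1) # genotyped founders
    id <- function(i) sprintf("%s_%02d", fam, i)
    nxt <- 0
    new_id <- function() {
      nxt <<- nxt + 1
      id(nxt)
    }
    fa <- new_id()
    mo <- new_id()
    members <- tibble(
      family_id = fam, individual_id = c(fa, mo),
      father_id = NA_character_, mother_id = NA_character_,
      sex = c("male", "female"), phenotype = "unknown",
      penetrance_exempt = FALSE,
      genotyped = c(n_gf >= 1, n_gf >= 2)
    )
    n_desc <- s - n_gf
    if (three_gen && n_desc >= 2) {
      n_children <- max(1, n_desc - sample(1:2, 1))
      n_gc <- n_desc - n_children
    } else {
      n_children <- n_desc
      n_gc <- 0
    }
    children <- character(n_children)
    for (i in seq_len(n_children)) {
      children[i] <- new_id()
      members <- bind_rows(members, tibble(
        family_id = fam, individual_id = children[i],
        father_id = fa, mother_id = mo,
        sex = sample(c("male", "female"), 1), phenotype = "unknown",
        penetrance_exempt = FALSE, genotyped = TRUE
      ))
    }
    if (n_gc > 0) {
      link <- children[1]
      link_sex <- members$sex[members$individual_id == link]
      spouse <- new_id()
      members <- bind_rows(members, tibble(
        family_id = fam, individual_id = spouse,
        father_id = NA_character_, mother_id = NA_character_,
        sex = if (link_sex == "male") "female" else "male",
        phenotype = "unknown", penetrance_exempt = FALSE, genotyped = FALSE
      ))
      gfa <- if (link_sex == "male") link else spouse
      gmo <- if (link_sex == "male") spouse else link
      for (i in seq_len(n_gc)) {
        members <- bind_rows(members, tibble(
          family_id = fam, individual_id = new_id(),
          father_id = gfa, mother_id = gmo,
          sex = sample(c("male", "female"), 1), phenotype = "unknown",
          penetrance_exempt = FALSE, genotyped = TRUE
        ))
      }
    }
    # an occasional relative who declined sequencing
    if (runif(1) < 0.15) {
      members <- bind_rows(members, tibble(
        family_id = fam, individual_id = new_id(),
        father_id = fa, mother_id = mo,
        sex = sample(c("male", "female"), 1), phenotype = "unknown",
        penetrance_exempt = FALSE, genotyped = FALSE
      ))
    }
    geno_idx <- which(members$genotyped)
    probs <- c(
      cfg$affected_fraction_target, cfg$suggestive_fraction,
      1 - cfg$affected_fraction_target - cfg$suggestive_fraction
    )
    members$phenotype[geno_idx] <- sample(
      c("affected", "suggestive", "unaffected"),
      length(geno_idx),
      replace = TRUE, prob = probs
    )
    if (!any(members$phenotype[geno_idx] == "affected")) {
      members$phenotype[sample(geno_idx, 1)] <- "affected"
    }
    members
  })
  validate_pedigree(bind_rows(rows))
}

# Drop one biallelic variant through every family given per-founder counts.
# Returns a named count vector over all genotyped samples.
drop_through_cohort <- function(ped, founder_count_fn) {
  out <- integer(0)
  for (fam in unique(ped$family_id)) {
    fam_ped <- ped[ped$family_id == fam, ]
    founders <- founder_ids(fam_ped)
    fc <- setNames(founder_count_fn(length(founders)), founders)
    counts <- gene_drop(fam_ped, fc)
    g <- fam_ped$individual_id[fam_ped$genotyped]
    out <- c(out, counts[g])
  }
  out
}

#' Simulate a complete synthetic exome cohort
#'
#' Generates pedigrees, a joint VCF, an annotation table, a low-complexity
#' region BED, a penetrance-exemption list and a ground-truth table, then
#' writes them to `dir` in the same formats the pipeline reads. Background
#' variants follow the configured MAF spectrum and are transmitted from
#' founder genotypes (drawn at the variant's MAF, so founder genotypes are in
#' Hardy-Weinberg proportions in expectation) by Mendelian gene dropping.
#' Planted variants get carrier patterns dictated by their [plant_spec()]
#' mode. Deliberate violators of each preparation and filter rule
#' (low-complexity region, Hardy-Weinberg, minor allele count, population
#' frequency, control frequency, synonymous effect, low CADD, excluded gene)
#' guarantee a nonzero removal tally per rule; the Hardy-Weinberg violators
#' are produced by explicit genotype-count distortion (every sample
#' heterozygous).
#'
#' The truth table records each variant's expected pipeline fate:
#' `qc_lcr` / `qc_hwe` / `qc_mac`, `filter_<rule>`,
#' `removed_unaffected_carrier`, `segregates` (with its target families) or
#' `background`.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return A list: `paths` (vcf, ped, annotation, lcr, truth, exemptions),
#'   `ped`, `truth`, `exemptions`, invisibly usable in-memory.
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir = tempfile("famseg_sim")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- simulate_pedigrees(cfg)
  with_seed(derive_seed(cfg$seed, "dataset"), {
    sim_dataset_impl(cfg, ped, dir)
  })
}

sim_dataset_impl <- function(cfg, ped, dir) {
  samples <- ped$individual_id[ped$genotyped]
  fams <- unique(ped$family_id)

  lcr <- tibble(
    chrom = c("1", "2", "7"),
    start = c(45000000L, 45500000L, 46000000L),
    end = c(45200000L, 45700000L, 46200000L)
  )

  nv <- cfg$n_violators_per_rule
  n_total <- cfg$n_background_variants + 2 * cfg$n_multiallelic +
    length(cfg$planted_variants) + 8 * nv
  pos_pool <- sort(sample.int(40000000L, n_total + 100))
  pos_i <- 0
  next_pos <- function() {
    pos_i <<- pos_i + 1
    pos_pool[pos_i]
  }
  bases <- c("A", "C", "G", "T")
  rand_snv <- function() sample(bases, 2)

  zero_geno <- setNames(rep(0L, length(samples)), samples)
  records <- list() # raw biallelic records: chrom,pos,ref,alt + geno + annotation
  truth <- list()
  add_record <- function(chrom, pos, ref, alt, geno, gene, effect, afs,
                         control_maf, cadd, category, fate, families = "") {
    rec <- c(
      list(
        chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
        rsid = NA_character_, geno = list(geno), gene = gene, effect = effect
      ),
      as.list(setNames(afs, paste0("af_", default_af_sources))),
      list(control_maf = control_maf, cadd_phred = cadd)
    )
    records[[length(records) + 1]] <<- rec
    truth[[length(truth) + 1]] <<- list(
      variant_id = variant_key(chrom, pos, ref, alt),
      category = category, gene = gene, expected_fate = fate,
      target_families = families
    )
  }
  rare_afs <- function() round(runif(length(default_af_sources), 0, 0.005), 5)
  noisy_afs <- function(maf) {
    pmin(1, pmax(0, round(maf * exp(runif(length(default_af_sources), -0.4, 0.4)), 5)))
  }

  # -- background variants ---------------------------------------------------
  lo <- log(cfg$background_maf_range[1])
  hi <- log(cfg$background_maf_range[2])
  n_bg_genes <- max(1, ceiling(cfg$n_background_variants / 1.5))
  for (i in seq_len(cfg$n_background_variants)) {
    maf <- exp(runif(1, lo, hi))
    al <- rand_snv()
    geno <- zero_geno
    dropped <- drop_through_cohort(ped, \(n) rbinom(n, 2, maf))
    geno[names(dropped)] <- dropped
    if (cfg$missing_genotype_rate > 0) {
      miss <- runif(length(geno)) < cfg$missing_genotype_rate
      geno[miss] <- NA_integer_
    }
    eff <- sample(
      c("nonsynonymous", "stopgain", "nonframeshift_indel", "unknown_effect", "splicing"),
      1,
      prob = c(0.7, 0.05, 0.1, 0.1, 0.05)
    )
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = al[1], alt = al[2], geno = geno,
      gene = sprintf("BG%04d", sample.int(n_bg_genes, 1)), effect = eff,
      afs = noisy_afs(maf), control_maf = round(maf * runif(1, 0.5, 1.5), 5),
      cadd = round(runif(1, 20, 40), 1),
      category = "background", fate = "background"
    )
  }

  # -- multiallelic background sites (written as two-alt VCF records) --------
  multi_sites <- list()
  for (i in seq_len(cfg$n_multiallelic)) {
    chrom <- as.character(sample(1:22, 1))
    pos <- next_pos()
    ref <- sample(bases, 1)
    alts <- sample(setdiff(bases, ref), 2)
    # per-sample allele pairs: drop two independent rare alts through families
    c1 <- zero_geno
    c2 <- zero_geno
    d1 <- drop_through_cohort(ped, \(n) rbinom(n, 1, 0.02))
    c1[names(d1)] <- d1
    d2 <- drop_through_cohort(ped, \(n) rbinom(n, 1, 0.02))
    c2[names(d2)] <- d2
    c2[c1 + c2 > 2] <- 0L # keep ploidy-consistent
    gt <- map2_chr(c1, c2, function(x, y) {
      a <- c(rep(1L, x), rep(2L, y), rep(0L, 2 - x - y))
      paste(sort(a), collapse = "/")
    })
    multi_sites[[i]] <- tibble(
      chrom = chrom, pos = as.integer(pos), rsid = NA_character_,
      ref = ref, alt = paste(alts, collapse = ","),
      gt = list(setNames(gt, samples))
    )
    for (k in 1:2) {
      geno <- if (k == 1) c1 else c2
      add_record(
        chrom = chrom, pos = pos, ref = ref, alt = alts[k], geno = geno,
        gene = sprintf("BGM%03d", i), effect = "nonsynonymous",
        afs = rare_afs(), control_maf = 0.002, cadd = round(runif(1, 20, 35), 1),
        category = "background_multiallelic", fate = "background"
      )
      records[[length(records)]]$from_multiallelic <- TRUE
    }
  }

  # -- rule violators --------------------------------------------------------
  one_carrier_geno <- function() {
    g <- zero_geno
    g[sample(samples, 1)] <- 1L
    g
  }
  for (i in seq_len(nv)) {
    lcr_row <- lcr[sample.int(nrow(lcr), 1), ]
    al <- rand_snv()
    add_record(
      chrom = lcr_row$chrom,
      pos = lcr_row$start + sample.int(lcr_row$end - lcr_row$start - 1, 1),
      ref = al[1], alt = al[2], geno = one_carrier_geno(),
      gene = sprintf("VLCR%02d", i), effect = "nonsynonymous",
      afs = rare_afs(), control_maf = 0.001, cadd = 25,
      category = "violator_lcr", fate = "qc_lcr"
    )
    al <- rand_snv()
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = al[1], alt = al[2],
      geno = setNames(rep(1L, length(samples)), samples), # every sample het
      gene = sprintf("VHWE%02d", i), effect = "nonsynonymous",
      afs = rare_afs(), control_maf = 0.001, cadd = 25,
      category = "violator_hwe", fate = "qc_hwe"
    )
    al <- rand_snv()
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = al[1], alt = al[2], geno = zero_geno,
      gene = sprintf("VMAC%02d", i), effect = "nonsynonymous",
      afs = rare_afs(), control_maf = 0.001, cadd = 25,
      category = "violator_mac", fate = "qc_mac"
    )
    al <- rand_snv()
    afs <- rare_afs()
    afs[3] <- 0.05 # common in one reference panel
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = al[1], alt = al[2], geno = one_carrier_geno(),
      gene = sprintf("VPOP%02d", i), effect = "nonsynonymous",
      afs = afs, control_maf = 0.001, cadd = 25,
      category = "violator_population_af", fate = "filter_population_af"
    )
    al <- rand_snv()
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = al[1], alt = al[2], geno = one_carrier_geno(),
      gene = sprintf("VCTL%02d", i), effect = "nonsynonymous",
      afs = rare_afs(), control_maf = 0.02, cadd = 25,
      category = "violator_control_maf", fate = "filter_control_maf"
    )
    al <- rand_snv()
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = al[1], alt = al[2], geno = one_carrier_geno(),
      gene = sprintf("VSYN%02d", i), effect = "synonymous",
      afs = rare_afs(), control_maf = 0.001, cadd = 30,
      category = "violator_effect", fate = "filter_effect_class"
    )
    al <- rand_snv()
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = al[1], alt = al[2], geno = one_carrier_geno(),
      gene = sprintf("VCAD%02d", i), effect = "nonsynonymous",
      afs = rare_afs(), control_maf = 0.001, cadd = 10,
      category = "violator_cadd", fate = "filter_cadd"
    )
    al <- rand_snv()
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = al[1], alt = al[2], geno = one_carrier_geno(),
      gene = sample(acmg_adult_onset_genes, 1), effect = "nonsynonymous",
      afs = rare_afs(), control_maf = 0.001, cadd = 25,
      category = "violator_acmg", fate = "filter_acmg_gene"
    )
  }

  # -- penetrance exemption candidates --------------------------------------
  exempt_ids <- character(0)
  needs_exempt <- unique(unlist(map(
    keep(cfg$planted_variants, \(p) isTRUE(p$exempt_carrier)),
    "target_families"
  )))
  for (fam in needs_exempt) {
    fam_ped <- ped[ped$family_id == fam, ]
    una <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "unaffected"]
    if (length(una) == 0) {
      # force one: reassign a suggestive/extra member, else the plant is infeasible
      cand <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "suggestive"]
      if (length(cand) == 0) {
        abort_config(sprintf(
          "family '%s' has no member that can serve as a penetrance-exempt unaffected individual", fam
        ))
      }
      ped$phenotype[ped$individual_id == cand[1]] <- "unaffected"
      una <- cand[1]
    }
    exempt_ids <- c(exempt_ids, una[1])
  }
  ped$penetrance_exempt <- ped$individual_id %in% exempt_ids

  # -- planted variants ------------------------------------------------------
  for (p in cfg$planted_variants) {
    missing_fam <- setdiff(p$target_families, fams)
    if (length(missing_fam) > 0) {
      abort_config(sprintf("plant targets unknown family '%s'", missing_fam[1]))
    }
    geno <- zero_geno
    flipped <- character(0)
    if (p$mode == "null") {
      dropped <- drop_through_cohort(ped, \(n) rbinom(n, 2, 0.02))
      geno[names(dropped)] <- dropped
    } else {
      for (fam in p$target_families) {
        fam_ped <- ped[ped$family_id == fam, ]
        # an incomplete plant needs a non-exempt unaffected member to carry it;
        # repurpose a suggestive (or surplus affected) member if none exists
        if (p$mode == "incomplete" &&
          !any(fam_ped$genotyped & fam_ped$phenotype == "unaffected" & !fam_ped$penetrance_exempt)) {
          sug <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "suggestive"]
          aff0 <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "affected"]
          flip_to_una <- if (length(sug) > 0) sug[1] else if (length(aff0) > 1) aff0[length(aff0)] else NULL
          if (is.null(flip_to_una)) {
            abort_config(sprintf(
              "incomplete plant in gene '%s' needs an unaffected member in family '%s'",
              p$gene, fam
            ))
          }
          ped$phenotype[ped$individual_id == flip_to_una] <- "unaffected"
          fam_ped <- ped[ped$family_id == fam, ]
        }
        aff <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "affected"]
        if (length(aff) == 0) {
          abort_config(sprintf(
            "plant in gene '%s' is infeasible: family '%s' has no affected member",
            p$gene, fam
          ))
        }
        geno[aff] <- 1L
        if (!is.null(p$hom_family) && fam == p$hom_family) geno[aff[1]] <- 2L
        sug <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "suggestive"]
        if (length(sug) > 0) geno[sug] <- rbinom(length(sug), 1, 0.5)
        if (p$mode == "incomplete") {
          una <- fam_ped$individual_id[
            fam_ped$genotyped & fam_ped$phenotype == "unaffected" & !fam_ped$penetrance_exempt
          ]
          if (length(una) == 0) {
            abort_config(sprintf(
              "incomplete plant in gene '%s' needs an unaffected member in family '%s'",
              p$gene, fam
            ))
          }
          geno[una[1]] <- 1L
        }
        if (p$exempt_carrier) {
          ex <- fam_ped$individual_id[fam_ped$penetrance_exempt]
          geno[ex] <- 1L
        }
        if (cfg$penetrance < 1) {
          for (a in aff) {
            if (runif(1) > cfg$penetrance) {
              ped$phenotype[ped$individual_id == a] <- "unaffected"
              flipped <- c(flipped, a)
            }
          }
        }
      }
    }
    if (p$indel) {
      ref <- paste0(sample(bases, 1), sample(bases, 1))
      alt <- substr(ref, 1, 1)
      if (substr(ref, 2, 2) == alt) alt <- substr(ref, 1, 1) # keep post-trim form
    } else {
      al <- rand_snv()
      ref <- al[1]
      alt <- al[2]
    }
    fate <- switch(p$mode,
      fully_segregating = "segregates",
      incomplete = "removed_unaffected_carrier",
      null = "background"
    )
    add_record(
      chrom = as.character(sample(1:22, 1)), pos = next_pos(),
      ref = ref, alt = alt, geno = geno, gene = p$gene, effect = p$effect,
      afs = rare_afs(), control_maf = round(runif(1, 0, 0.005), 5),
      cadd = p$cadd,
      category = paste0("planted_", p$mode), fate = fate,
      families = paste(p$target_families, collapse = ",")
    )
    if (length(flipped) > 0) {
      truth[[length(truth)]]$exemption_candidates <- paste(flipped, collapse = ",")
      exempt_ids <- c(exempt_ids, flipped)
    }
  }

  exempt_ids <- unique(exempt_ids)
  ped$penetrance_exempt <- ped$individual_id %in% exempt_ids

  # -- assemble and write ----------------------------------------------------
  variants <- bind_rows(map(records, \(r) as_tibble(r[setdiff(names(r), "from_multiallelic")])))
  variants$variant_id <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants$is_indel <- nchar(variants$ref) != nchar(variants$alt)
  variants <- order_variants(variants)
  attr(variants, "samples") <- samples

  truth_tbl <- bind_rows(map(truth, function(t) {
    tibble(
      variant_id = t$variant_id, category = t$category, gene = t$gene,
      expected_fate = t$expected_fate, target_families = t$target_families,
      exemption_candidates = t$exemption_candidates %||% ""
    )
  })) |> arrange(.data$variant_id)

  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    annotation = file.path(dir, "annotation.tsv"),
    lcr = file.path(dir, "lcr.bed"),
    truth = file.path(dir, "truth.tsv"),
    exemptions = file.path(dir, "exemptions.txt")
  )
  write_sim_vcf(variants, multi_sites, samples, paths$vcf)
  write_ped(ped, paths$ped)
  write_annotation(variants, paths$annotation)
  write_bed(lcr, paths$lcr)
  readr::write_tsv(truth_tbl, paths$truth, progress = FALSE)
  readr::write_lines(unique(exempt_ids), paths$exemptions)

  list(
    paths = paths, ped = ped, variants = variants, truth = truth_tbl,
    lcr = lcr, exemptions = unique(exempt_ids), samples = samples
  )
}

# Write the simulated cohort VCF: biallelic records from count vectors plus
# the raw multiallelic sites, position-sorted.
write_sim_vcf <- function(variants, multi_sites, samples, path) {
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  multi <- bind_rows(multi_sites)
  is_multi_part <- variants$variant_id %in% unlist(map(multi_sites, function(m) {
    alts <- strsplit(m$alt, ",")[[1]]
    variant_key(m$chrom, m$pos, m$ref, alts)
  }))
  bi <- variants[!is_multi_part, ]
  bi_lines <- tibble(
    chrom = bi$chrom, pos = bi$pos,
    line = pmap_chr(
      list(bi$chrom, bi$pos, bi$ref, bi$alt, bi$geno),
      function(chrom, pos, ref, alt, geno) {
        counts <- geno[samples]
        gts <- ifelse(is.na(counts), "./.", gt_of[as.character(counts)])
        paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts), collapse = "\t")
      }
    )
  )
  multi_lines <- if (nrow(multi) > 0) {
    tibble(
      chrom = multi$chrom, pos = multi$pos,
      line = pmap_chr(
        list(multi$chrom, multi$pos, multi$ref, multi$alt, multi$gt),
        function(chrom, pos, ref, alt, gt) {
          paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gt[samples]),
            collapse = "\t"
          )
        }
      )
    )
  } else {
    tibble(chrom = character(), pos = integer(), line = character())
  }
  body <- bind_rows(bi_lines, multi_lines) |> arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
      collapse = "\t"
    )
  )
  readr::write_lines(c(header, body$line), path)
  invisible(path)
}
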