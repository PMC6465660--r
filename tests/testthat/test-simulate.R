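test_that("simulated pedigrees meet the configured shape", {
  cfg <- simulation_config(seed = 303)
  ped <- simulate_pedigrees(cfg)
  expect_equal(dplyr::n_distinct(ped$family_id), 18)
  per_fam <- ped |>
    dplyr::filter(.data$genotyped) |>
    dplyr::count(.data$family_id)
  expect_true(all(per_fam$n >= 2 & per_fam$n <= 7))
  expect_true(sum(per_fam$n) >= 36 && sum(per_fam$n) <= 126)
  # at least one affected genotyped member everywhere
  aff <- ped |>
    dplyr::filter(.data$genotyped, .data$phenotype == "affected") |>
    dplyr::count(.data$family_id)
  expect_equal(nrow(aff), 18)
  # structural validity (parents defined, acyclic) is enforced by the builder
  expect_silent(validate_pedigree(ped))
  # parents precede children topologically in every family
  for (fam in unique(ped$family_id)) {
    fp <- ped[ped$family_id == fam, ]
    ord <- famseg:::topo_order(fp)
    for (i in seq_len(nrow(fp))) {
      if (!is.na(fp$father_id[i])) {
        expect_lt(match(fp$father_id[i], ord), match(fp$individual_id[i], ord))
        expect_lt(match(fp$mother_id[i], ord), match(fp$individual_id[i], ord))
      }
    }
  }
})

test_that("a fixed seed reproduces byte-identical simulated files", {
  cfg <- simulation_config(seed = 99, n_background_variants = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg, dir = d1)
  s2 <- simulate_dataset(cfg, dir = d2)
  for (nm in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]))
  }
})

test_that("emitted files re-parse to the generator's in-memory state", {
  sim <- default_sim()
  ped2 <- read_pedigree(sim$paths$ped, exempt = sim$exemptions) |>
    align_samples(sim$samples)
  expect_equal(as.data.frame(ped2), as.data.frame(sim$ped))
  v2 <- parse_variant_table(sim$paths$vcf, sim$paths$annotation)
  expect_setequal(v2$variant_id, sim$variants$variant_id)
  j <- dplyr::inner_join(v2, sim$variants, by = "variant_id")
  expect_true(all(purrr::map2_lgl(
    j$geno.x, j$geno.y,
    \(a, b) identical(as.integer(a[sim$samples]), as.integer(b[sim$samples]))
  )))
  expect_equal(j$cadd_phred.x, j$cadd_phred.y)
  expect_equal(j$gene.x, j$gene.y)
  expect_equal(j$effect.x, j$effect.y)
  expect_equal(j$af_exac_all.x, j$af_exac_all.y)
  lcr2 <- read_bed_regions(sim$paths$lcr)
  expect_equal(lcr2, sim$lcr)
})

test_that("every preparation and filter rule removes at least one truth-flagged variant", {
  sim <- default_sim()
  prepped <- qc_prefilter(sim$variants, sim$lcr, family_samples = sim$samples)
  qc_removed <- attr(prepped, "removed")
  truth <- sim$truth
  for (rule in c("lcr", "hwe", "mac")) {
    flagged <- truth$variant_id[truth$expected_fate == paste0("qc_", rule)]
    expect_gt(length(flagged), 0)
    expect_true(all(flagged %in% qc_removed$variant_id[qc_removed$rule == rule]))
  }
  filtered <- apply_rare_filters(prepped)
  dec <- attr(filtered, "decisions")
  for (rule in c("population_af", "control_maf", "effect_class", "cadd", "acmg_gene")) {
    flagged <- truth$variant_id[truth$expected_fate == paste0("filter_", rule)]
    expect_gt(length(flagged), 0)
    expect_true(all(flagged %in% dec$variant_id[dec$failed_rule == rule]))
  }
})

test_that("planted variants reach their scripted pipeline fate", {
  sim <- default_sim()
  prepped <- qc_prefilter(sim$variants, sim$lcr, family_samples = sim$samples)
  filtered <- apply_rare_filters(prepped)
  kept <- remove_global_unaffected_carriers(filtered, sim$ped)
  truth <- sim$truth
  # incomplete plants die at the unaffected-carrier rule
  inc <- truth$variant_id[truth$expected_fate == "removed_unaffected_carrier"]
  expect_gt(length(inc), 0)
  expect_true(all(inc %in% attr(kept, "removed")))
  # fully segregating plants appear in exactly their target families
  res <- segregating_variants(kept, sim$ped)
  seg_truth <- truth[truth$expected_fate == "segregates", ]
  for (i in seq_len(nrow(seg_truth))) {
    want <- sort(strsplit(seg_truth$target_families[i], ",")[[1]])
    got <- sort(res$family_id[res$variant_id == seg_truth$variant_id[i]])
    expect_equal(got, want)
  }
  # the exempt-carrier plant survived despite its unaffected carrier
  exempt_plant <- truth$variant_id[truth$category == "planted_fully_segregating" &
    grepl("F14", truth$target_families)]
  expect_true(all(exempt_plant %in% kept$variant_id))
})

test_that("infeasible plants and configurations are rejected", {
  expect_error(simulation_config(family_size_range = c(1, 7)),
    class = "famseg_config_error"
  )
  expect_error(simulation_config(affected_fraction_target = 0.9,
    suggestive_fraction = 0.3
  ), class = "famseg_config_error")
  cfg <- simulation_config(
    n_families = 2, n_background_variants = 5,
    planted_variants = list(plant_spec("F99", "GX"))
  )
  expect_error(simulate_dataset(cfg, dir = withr::local_tempdir()),
    class = "famseg_config_error"
  )
  expect_error(plant_spec("F1", "G", cadd = 10), class = "famseg_config_error")
  expect_error(plant_spec("F1", "G", cadd = NA), class = "famseg_config_error")
})
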