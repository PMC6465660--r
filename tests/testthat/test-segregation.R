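ped2fam <- function() {
  dplyr::bind_rows(
    nuclear_ped("FA", child_pheno = c("affected", "unaffected", "suggestive")),
    nuclear_ped("FB", child_pheno = c("affected", "affected", "unaffected"))
  ) |> dplyr::mutate(individual_id = paste(family_id, individual_id, sep = "_"),
    father_id = ifelse(is.na(father_id), NA, paste(family_id, father_id, sep = "_")),
    mother_id = ifelse(is.na(mother_id), NA, paste(family_id, mother_id, sep = "_"))
  )
}

geno_for <- function(ped, carriers, value = 1L) {
  g <- setNames(rep(0L, sum(ped$genotyped)), ped$individual_id[ped$genotyped])
  g[carriers] <- value
  g
}

test_that("any non-exempt unaffected carrier anywhere removes a variant", {
  ped <- ped2fam()
  tb <- variant_tbl(list(
    geno_for(ped, "FA_c2"), # unaffected carrier in family A
    geno_for(ped, "FA_c3"), # suggestive carrier only
    geno_for(ped, c("FA_c1", "FB_c1")) # affected carriers only
  ))
  out <- remove_global_unaffected_carriers(tb, ped)
  expect_equal(out$variant_id, tb$variant_id[2:3])
  expect_equal(attr(out, "removed"), tb$variant_id[1])
})

test_that("penetrance-exempt unaffected carriers do not trigger removal", {
  ped <- ped2fam()
  ped$penetrance_exempt[ped$individual_id == "FA_c2"] <- TRUE
  tb <- variant_tbl(list(geno_for(ped, "FA_c2"), geno_for(ped, "FB_c3")))
  out <- remove_global_unaffected_carriers(tb, ped)
  expect_equal(out$variant_id, tb$variant_id[1])
})

test_that("segregation status follows the carrier contract", {
  fam <- nuclear_ped("F", child_pheno = c("affected", "affected", "unaffected"))
  st <- function(g) classify_segregation(fam, g)
  hom_ref <- setNames(rep(0L, 5), fam$individual_id)
  expect_equal(st(`[<-`(hom_ref, c("c1", "c2"), 1L)), "segregates")
  expect_equal(st(`[<-`(hom_ref, "c1", 1L)), "fails") # one affected hom-ref
  g <- `[<-`(hom_ref, c("c1", "c2"), c(2L, 1L))
  g["c3"] <- 1L
  expect_equal(st(g), "incomplete") # all affected carry, an unaffected carries
  g2 <- `[<-`(hom_ref, c("c1", "c2"), 1L)
  g2["c1"] <- NA_integer_
  expect_equal(st(g2), "fails") # missing genotype in an affected fails
  g3 <- `[<-`(hom_ref, c("c1", "c2"), 1L)
  g3["c3"] <- NA_integer_
  expect_equal(st(g3), "segregates") # missing in unaffected is not carriage
  no_aff <- nuclear_ped("F", child_pheno = rep("suggestive", 3))
  expect_error(classify_segregation(no_aff, hom_ref),
    class = "famseg_not_evaluable_error"
  )
})

test_that("a family with no genotyped unaffected members passes vacuously", {
  fam <- nuclear_ped("F",
    n_children = 1, child_pheno = "affected",
    founder_pheno = c("suggestive", "unknown")
  )
  tb <- variant_tbl(list(setNames(c(0L, 0L, 1L), fam$individual_id)))
  res <- segregating_variants(tb, fam)
  expect_equal(nrow(res), 1)
  expect_equal(res$family_id, "F")
})

test_that("per-family segregation matches a brute-force recount", {
  sim <- default_sim()
  kept <- sim$variants |>
    remove_global_unaffected_carriers(sim$ped)
  res <- segregating_variants(kept, sim$ped)
  # oracle: direct nested-loop evaluation of the rule
  for (fam in unique(sim$ped$family_id)) {
    fp <- sim$ped[sim$ped$family_id == fam, ]
    aff <- fp$individual_id[fp$genotyped & fp$phenotype == "affected"]
    una <- fp$individual_id[fp$genotyped & fp$phenotype == "unaffected" &
      !fp$penetrance_exempt]
    if (length(aff) == 0) next
    want <- character(0)
    for (i in seq_len(nrow(kept))) {
      g <- kept$geno[[i]]
      ok <- TRUE
      for (a in aff) if (is.na(g[[a]]) || g[[a]] < 1) ok <- FALSE
      for (u in una) if (!is.na(g[[u]]) && g[[u]] >= 1) ok <- FALSE
      if (ok) want <- c(want, kept$variant_id[i])
    }
    expect_setequal(res$variant_id[res$family_id == fam], want)
  }
  # reported variants are carried by every genotyped affected member
  for (i in seq_len(nrow(res))) {
    fp <- sim$ped[sim$ped$family_id == res$family_id[i], ]
    aff <- fp$individual_id[fp$genotyped & fp$phenotype == "affected"]
    g <- kept$geno[[match(res$variant_id[i], kept$variant_id)]]
    expect_true(all(!is.na(g[aff]) & g[aff] >= 1))
  }
})

test_that("removing an unaffected member never shrinks a family's segregating set", {
  sim <- default_sim()
  kept <- remove_global_unaffected_carriers(sim$variants, sim$ped)
  res <- segregating_variants(kept, sim$ped)
  ped <- sim$ped
  una <- ped[ped$genotyped & ped$phenotype == "unaffected", ]
  expect_gt(nrow(una), 0)
  drop_id <- una$individual_id[1]
  fam <- una$family_id[1]
  ped_less <- ped[ped$individual_id != drop_id | ped$family_id != fam, ]
  # only drop leaves (members who are no one's parent) to keep links valid
  if (drop_id %in% c(ped$father_id, ped$mother_id)) {
    ped_less <- ped
    ped_less$genotyped[ped_less$individual_id == drop_id] <- FALSE
  }
  res_less <- segregating_variants(kept, ped_less)
  before <- res$variant_id[res$family_id == fam]
  after <- res_less$variant_id[res_less$family_id == fam]
  expect_true(all(before %in% after))
})

test_that("segregation output ordering is deterministic", {
  sim <- default_sim()
  kept <- remove_global_unaffected_carriers(sim$variants, sim$ped)
  res <- segregating_variants(kept, sim$ped)
  reord <- segregating_variants(kept[rev(seq_len(nrow(kept))), ], sim$ped)
  expect_equal(res, reord)
})
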