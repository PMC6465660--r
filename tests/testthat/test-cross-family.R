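seg_row <- function(family, variant, gene, hom = FALSE) {
  tibble::tibble(
    family_id = family, variant_id = variant, gene = gene, carrier_hom = hom
  )
}

test_that("shared variants require at least two families and keep all of them", {
  res <- dplyr::bind_rows(
    seg_row("F1", "v1", "GA"),
    seg_row("F2", "v1", "GA"),
    seg_row("F3", "v1", "GA"),
    seg_row("F1", "v2", "GB")
  )
  sh <- shared_variants(res)
  expect_equal(nrow(sh), 1)
  expect_equal(sh$families[[1]], c("F1", "F2", "F3"))
  expect_false("v2" %in% sh$variant_id)
  # permutation of family order changes nothing
  sh2 <- shared_variants(res[sample(nrow(res)), ])
  expect_equal(sh, sh2)
})

test_that("shared and single-family variants partition the segregating union", {
  sim <- default_sim()
  kept <- remove_global_unaffected_carriers(
    apply_rare_filters(qc_prefilter(sim$variants, sim$lcr, sim$samples)),
    sim$ped
  )
  res <- segregating_variants(kept, sim$ped)
  sh <- shared_variants(res)
  per_var <- res |>
    dplyr::distinct(.data$variant_id, .data$family_id) |>
    dplyr::count(.data$variant_id)
  singles <- per_var$variant_id[per_var$n == 1]
  expect_setequal(c(sh$variant_id, singles), unique(res$variant_id))
  expect_length(intersect(sh$variant_id, singles), 0)
})

test_that("multi-variant genes pool families across variants", {
  res <- dplyr::bind_rows(
    seg_row("F6", "vA", "RB"), # one variant in family 6
    seg_row("F7", "vB", "RB"), # two same-family variants in family 7
    seg_row("F7", "vC", "RB"),
    seg_row("F5", "vD", "KC"), # two variants, both only family 5
    seg_row("F5", "vE", "KC"),
    seg_row("F1", "vF", "ZZ") # single variant
  )
  mg <- multi_variant_genes(res)
  expect_equal(mg$gene, "RB")
  expect_equal(mg$families[[1]], c("F6", "F7"))
  expect_equal(mg$n_variants, 3)
  # strict reading: every variant itself in >= 2 families
  expect_equal(nrow(multi_variant_genes(res, strict = TRUE)), 0)
  res_strict <- dplyr::bind_rows(res, seg_row("F8", "vB", "RB"), seg_row("F8", "vC", "RB"))
  expect_equal(multi_variant_genes(res_strict, strict = TRUE)$gene, "RB")
  # the same-family gene lands in the within-family report instead
  wf <- within_family_multihit(res)
  expect_true(all(c("KC", "RB") %in% wf$gene))
  expect_equal(wf$n_variants[wf$gene == "KC"], 2)
  # family order permutation invariance
  expect_equal(mg, multi_variant_genes(res[sample(nrow(res)), ]))
})

test_that("cohort summary reports exact and rounded means", {
  counts <- tibble::tibble(
    family_id = "F1", n_affected = 2L, n_suggestive = 0L,
    n_unaffected = 1L, n_segregating = 5L
  )
  s <- cohort_summary(counts)
  expect_equal(s$mean_segregating, 5)
  expect_equal(s$min_segregating, 5)
  expect_equal(s$max_segregating, 5)
  expect_equal(s$n_individuals, 3)
  expect_error(cohort_summary(counts[0, ]), class = "famseg_domain_error")
  g <- glance(s)
  expect_equal(g$mean_segregating_rounded, 5L)
  expect_equal(nrow(tidy(s)), 1)
})

test_that("allelic odds ratio follows the cross-product formula", {
  r <- allelic_odds_ratio(10, 90, 5, 195)
  expect_equal(r$odds_ratio, (10 * 195) / (90 * 5))
  expect_equal(r$odds_ratio, 4.33, tolerance = 1e-3)
  expect_false(r$corrected)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  same <- allelic_odds_ratio(7, 13, 7, 13)
  expect_equal(same$odds_ratio, 1)
  expect_error(allelic_odds_ratio(0, 0, 5, 5), class = "famseg_domain_error")
  t <- tidy(r)
  expect_equal(t$odds_ratio, r$odds_ratio)
})

test_that("zero cells trigger the +0.5 continuity correction", {
  r <- allelic_odds_ratio(3, 97, 0, 200)
  expect_true(r$corrected)
  or_want <- (3.5 * 200.5) / (97.5 * 0.5)
  expect_equal(r$odds_ratio, or_want)
  se <- sqrt(1 / 3.5 + 1 / 97.5 + 1 / 0.5 + 1 / 200.5)
  expect_equal(r$ci_low, exp(log(or_want) - qnorm(0.975) * se))
  expect_equal(r$ci_high, exp(log(or_want) + qnorm(0.975) * se))
  # p-value from the uncorrected exact enumeration
  expect_equal(r$p_value, fisher_oracle(3, 97, 0, 200), tolerance = 1e-9)
})

test_that("Fisher p matches hypergeometric enumeration across random tables", {
  set.seed(404)
  for (rep in 1:40) {
    a <- sample(0:20, 1); b <- sample(1:60, 1)
    c <- sample(0:20, 1); d <- sample(1:60, 1)
    if (a + c == 0) next
    r <- allelic_odds_ratio(a, b, c, d)
    expect_equal(r$p_value, fisher_oracle(a, b, c, d), tolerance = 1e-7)
  }
})
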