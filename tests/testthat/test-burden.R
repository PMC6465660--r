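test_that("gene dropping respects Mendelian transmission constraints", {
  ped <- nuclear_ped("F", n_children = 2)
  set.seed(501)
  none <- gene_drop(ped, c(p1 = 0L, p2 = 0L))
  expect_true(all(none == 0L))
  hom <- gene_drop(ped, c(p1 = 2L, p2 = 0L))
  expect_true(all(hom[c("c1", "c2")] >= 1L)) # obligate transmission
  expect_error(gene_drop(ped, c(p1 = 1L)), class = "famseg_config_error")
  expect_error(gene_drop(ped, c(p1 = 3L, p2 = 0L)), class = "famseg_config_error")
})

test_that("a het founder transmits to a child half the time", {
  ped <- nuclear_ped("F", n_children = 1)
  set.seed(502)
  n <- 10000
  hits <- sum(replicate(n, gene_drop(ped, c(p1 = 1L, p2 = 0L))[["c1"]] >= 1L))
  se <- sqrt(0.25 / n)
  expect_lt(abs(hits / n - 0.5), 3 * se)
})

test_that("the nuclear-family burden p equals the exact transmission probability", {
  # het founder, three affected carrier children: exact enumeration over the
  # 2^3 transmission patterns gives P(all carry) = 1/8
  ped <- nuclear_ped("F", n_children = 3, child_pheno = rep("affected", 3))
  tb <- variant_tbl(list(c(p1 = 1L, p2 = 0L, c1 = 1L, c2 = 1L, c3 = 1L)),
    genes = "G1"
  )
  n_iter <- 20000
  r <- family_burden_test(tb, ped, gene = "G1",
    cfg = gene_drop_config(n_iterations = n_iter, seed = 9)
  )
  expect_equal(r$observed_statistic, 3L)
  mc_se <- sqrt(0.125 * 0.875 / n_iter)
  expect_lt(abs(r$p_value - 0.125), 3 * mc_se)
})

test_that("burden results are deterministic and order-invariant", {
  ped <- nuclear_ped("F", n_children = 3)
  tb <- dplyr::bind_rows(
    variant_tbl(list(c(p1 = 1L, p2 = 0L, c1 = 1L, c2 = 1L, c3 = 0L)), genes = "GA"),
    variant_tbl(list(c(p1 = 0L, p2 = 1L, c1 = 0L, c2 = 1L, c3 = 1L)), genes = "GB")
  )
  tb$variant_id <- paste0(tb$variant_id, "_", tb$gene)
  cfg <- gene_drop_config(n_iterations = 2000, seed = 31)
  s1 <- burden_scan(tb, ped, cfg = cfg)
  s2 <- burden_scan(tb, ped, genes = c("GB", "GA"), cfg = cfg)
  expect_equal(s1$p_value, s2$p_value[match(s1$gene, s2$gene)])
  s3 <- burden_scan(tb, ped, cfg = cfg)
  expect_identical(s1$p_value, s3$p_value)
  g <- glance(s1)
  expect_equal(g$n_genes, 2L)
})

test_that("degenerate burden inputs give defined results", {
  ped <- nuclear_ped("F", n_children = 2)
  no_var <- variant_tbl(list(), genes = character(0))[0, ]
  r <- family_burden_test(no_var, ped, gene = "EMPTY")
  expect_equal(r$observed_statistic, 0L)
  expect_equal(r$p_value, 1)
  # zero carriers anywhere
  tb <- variant_tbl(list(c(p1 = 0L, p2 = 0L, c1 = 0L, c2 = 0L)), genes = "G0")
  r0 <- family_burden_test(tb, ped, gene = "G0",
    cfg = gene_drop_config(n_iterations = 200, seed = 1)
  )
  expect_equal(r0$p_value, 1)
  expect_gte(r0$p_value, 1 / 201)
})

test_that("adding an affected carrier never increases the burden p", {
  ped <- nuclear_ped("F", n_children = 4, child_pheno = rep("affected", 4))
  base_geno <- c(p1 = 1L, p2 = 0L, c1 = 1L, c2 = 1L, c3 = 0L, c4 = 0L)
  more_geno <- base_geno
  more_geno["c3"] <- 1L
  cfg <- gene_drop_config(n_iterations = 5000, seed = 77)
  p_base <- family_burden_test(variant_tbl(list(base_geno), genes = "G"),
    ped, gene = "G", cfg = cfg
  )$p_value
  p_more <- family_burden_test(variant_tbl(list(more_geno), genes = "G"),
    ped, gene = "G", cfg = cfg
  )$p_value
  expect_lte(p_more, p_base)
})

test_that("ungenotyped founders are imputed conditional on observed carriage", {
  # founders unsequenced; two affected carrier children among three genotyped.
  ped <- nuclear_ped("F", n_children = 3,
    child_pheno = c("affected", "affected", "unaffected"),
    founder_genotyped = FALSE
  )
  tb <- variant_tbl(list(c(c1 = 1L, c2 = 1L, c3 = 0L)), genes = "G")
  r <- family_burden_test(tb, ped, gene = "G",
    cfg = gene_drop_config(n_iterations = 20000, seed = 5)
  )
  expect_equal(r$observed_statistic, 2L)
  # conditional on >=1 of the 3 children carrying (forced het founder), the
  # exact probability of (both affected carry, the unaffected does not) is
  # (1/8) / (7/8) = 1/7; S >= 2 is exactly that event
  mc_se <- sqrt((1 / 7) * (6 / 7) / 20000)
  expect_lt(abs(r$p_value - 1 / 7), 4 * mc_se)
})

test_that("the permutation p-value respects its lower bound", {
  ped <- nuclear_ped("F", n_children = 3, child_pheno = rep("affected", 3))
  tb <- variant_tbl(list(c(p1 = 1L, p2 = 0L, c1 = 1L, c2 = 1L, c3 = 1L)), genes = "G")
  r <- family_burden_test(tb, ped, gene = "G",
    cfg = gene_drop_config(n_iterations = 50, seed = 2)
  )
  expect_gte(r$p_value, 1 / 51)
  expect_lte(r$p_value, 1)
})
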