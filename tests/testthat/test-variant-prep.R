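test_that("biallelic sites pass through decomposition unchanged", {
  sites <- tibble::tibble(
    chrom = "1", pos = 100L, rsid = "rs1", ref = "A", alt = "T",
    gt = list(c(S1 = "0/1", S2 = "0/0"))
  )
  out <- decompose_multiallelic(sites)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 100L)
  expect_equal(as.integer(out$geno[[1]]), c(1L, 0L))
})

test_that("multiallelic genotypes are recounted per alt allele", {
  # ref A, alts C,T; GT 1/2 carries one copy of each alt
  sites <- tibble::tibble(
    chrom = "1", pos = 100L, rsid = NA_character_, ref = "A", alt = "C,T",
    gt = list(c(S1 = "1/2", S2 = "2/2", S3 = "0/1", S4 = "./."))
  )
  out <- decompose_multiallelic(sites)
  expect_equal(nrow(out), 2)
  expect_equal(as.integer(out$geno[[1]]), c(1L, 0L, 1L, NA))
  expect_equal(as.integer(out$geno[[2]]), c(1L, 2L, 0L, NA))
})

test_that("decomposition conserves total alt-allele copies", {
  set.seed(401)
  for (rep in 1:25) {
    n_alt <- sample(1:3, 1)
    n_samp <- sample(2:6, 1)
    gts <- replicate(n_samp, {
      if (runif(1) < 0.1) {
        "./."
      } else {
        paste(sort(sample(0:n_alt, 2, replace = TRUE)), collapse = "/")
      }
    })
    names(gts) <- paste0("S", seq_len(n_samp))
    sites <- tibble::tibble(
      chrom = "1", pos = 500L, rsid = NA_character_, ref = "A",
      alt = paste(sample(c("C", "G", "T"), n_alt), collapse = ","),
      gt = list(gts)
    )
    out <- decompose_multiallelic(sites)
    # oracle: recount non-reference allele copies straight from the GT strings
    expected <- sum(vapply(gts, function(g) {
      if (g == "./.") return(0L)
      sum(as.integer(strsplit(g, "/")[[1]]) > 0L)
    }, integer(1)))
    got <- sum(vapply(out$geno, function(g) sum(g, na.rm = TRUE), numeric(1)))
    expect_equal(got, expected)
  }
})

test_that("shared allele bases are trimmed prefix-first, advancing the position", {
  sites <- tibble::tibble(
    chrom = "1", pos = 100L, rsid = NA_character_, ref = "ACG", alt = "AG",
    gt = list(c(S1 = "0/1"))
  )
  out <- decompose_multiallelic(sites)
  expect_equal(out$pos, 101L)
  expect_equal(out$ref, "CG")
  expect_equal(out$alt, "G")

  set.seed(402)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    ref <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    want <- trim_oracle(150L, ref, alt)
    sites <- tibble::tibble(
      chrom = "1", pos = 150L, rsid = NA_character_, ref = ref, alt = alt,
      gt = list(c(S1 = "0/1"))
    )
    out <- decompose_multiallelic(sites)
    expect_equal(out$pos, as.integer(want$pos))
    expect_equal(out$ref, want$ref)
    expect_equal(out$alt, want$alt)
  }
})

test_that("Hardy-Weinberg exact test handles edge cases and symmetry", {
  expect_equal(hwe_exact_p(10, 0, 0), 1)
  expect_error(hwe_exact_p(-1, 0, 1), class = "famseg_domain_error")
  expect_error(hwe_exact_p(0, 0, 0), class = "famseg_domain_error")
  set.seed(403)
  for (rep in 1:30) {
    a <- sample(0:30, 1)
    h <- sample(0:30, 1)
    b <- sample(0:30, 1)
    if (a + h + b == 0) next
    expect_equal(hwe_exact_p(a, h, b), hwe_exact_p(b, h, a))
  }
})

test_that("Hardy-Weinberg exact p matches independent enumeration", {
  # extreme excess heterozygosity at n = 100
  expect_equal(hwe_exact_p(1, 98, 1), hwe_oracle(1, 98, 1), tolerance = 1e-12)
  # brute-force allele-placement oracle at tiny n
  for (cfg in list(c(1, 2, 1), c(0, 4, 1), c(3, 1, 1), c(2, 2, 2), c(1, 0, 4))) {
    expect_equal(
      hwe_exact_p(cfg[1], cfg[2], cfg[3]),
      hwe_oracle_bruteforce(cfg[1], cfg[2], cfg[3]),
      tolerance = 1e-10
    )
  }
  # exhaustive sweep at moderate n (the full-depth sweep runs with the
  # acceptance checks)
  for (n in c(2, 5, 17, 40)) {
    for (a in 0:n) {
      for (h in 0:(n - a)) {
        b <- n - a - h
        expect_equal(hwe_exact_p(a, h, b), hwe_oracle(a, h, b), tolerance = 1e-12)
      }
    }
  }
})

test_that("quality prefilter removes LCR, HWE and zero-MAC variants in order", {
  samples <- paste0("S", 1:8)
  het_all <- setNames(rep(1L, 8), samples)
  hom_ref <- setNames(rep(0L, 8), samples)
  one_het <- `[<-`(hom_ref, "S1", 1L)
  tb <- variant_tbl(
    list(one_het, het_all, hom_ref, one_het),
    chrom = c("9", "2", "3", "4")
  )
  lcr <- tibble::tibble(chrom = "9", start = 1000L, end = 1100L)
  hwe_thr <- hwe_exact_p(0, 8, 0) * (1 + 1e-9) # all-het lies just below
  out <- qc_prefilter(tb, lcr, family_samples = samples, hwe_threshold = hwe_thr)
  expect_equal(out$variant_id, tb$variant_id[4])
  expect_equal(
    as.integer(attr(out, "tally")[c("lcr", "hwe", "mac")]),
    c(1L, 1L, 1L)
  )
  removed <- attr(out, "removed")
  expect_equal(removed$rule[match(tb$variant_id[1:3], removed$variant_id)],
    c("lcr", "hwe", "mac"))
})

test_that("a variant exactly at the HWE threshold is retained", {
  samples <- paste0("S", 1:8)
  het_all <- setNames(rep(1L, 8), samples)
  tb <- variant_tbl(list(het_all))
  p_exact <- hwe_exact_p(0, 8, 0)
  empty_lcr <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  kept <- qc_prefilter(tb, empty_lcr, family_samples = samples, hwe_threshold = p_exact)
  expect_equal(nrow(kept), 1) # strict "<": equality retains
  dropped <- qc_prefilter(tb, empty_lcr,
    family_samples = samples,
    hwe_threshold = p_exact * (1 + 1e-9)
  )
  expect_equal(nrow(dropped), 0)
})

test_that("quality prefilter is idempotent and needs a family sample set", {
  sim <- default_sim()
  lcr <- sim$lcr
  once <- qc_prefilter(sim$variants, lcr, family_samples = sim$samples)
  twice <- qc_prefilter(once, lcr, family_samples = sim$samples)
  expect_equal(twice$variant_id, once$variant_id)
  expect_equal(sum(attr(twice, "tally")), 0L)
  expect_error(
    qc_prefilter(sim$variants, lcr, family_samples = character()),
    class = "famseg_config_error"
  )
})
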