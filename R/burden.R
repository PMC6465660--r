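#' Gene-dropping permutation configuration
#'
#' @param n_iterations Number of Monte-Carlo gene drops (default 100000).
#' @param seed Master seed; per-gene streams are derived from it so results
#'   do not depend on the order genes are evaluated.
#' @param statistic Burden statistic; currently the affected-minus-unaffected
#'   carrier count.
#' @return A list of class `famseg_genedrop_config`.
#' @export
gene_drop_config <- function(n_iterations = 100000, seed = 1,
                             statistic = "affected_minus_unaffected_carriers") {
  if (n_iterations < 1) abort_config("n_iterations must be at least 1")
  statistic <- match.arg(statistic)
  structure(
    list(n_iterations = as.integer(n_iterations), seed = as.integer(seed),
         statistic = statistic),
    class = "famseg_genedrop_config"
  )
}

# Founder ancestors (including self for founders) of every member.
founder_ancestors <- function(fam_ped) {
  ord <- topo_order(fam_ped)
  anc <- list()
  for (id in ord) {
    row <- fam_ped[fam_ped$individual_id == id, ]
    if (is.na(row$father_id)) {
      anc[[id]] <- id
    } else {
      anc[[id]] <- unique(c(anc[[row$father_id]], anc[[row$mother_id]]))
    }
  }
  anc
}

# Vectorised Mendelian gene drop. f1, f2: n_iter x n_founders 0/1 allele
# matrices (columns named by founder id). Returns n_iter x n_members count
# matrix. One allele is drawn uniformly from each parent's two alleles,
# independently across meioses and iterations.
gene_drop_core <- function(fam_ped, f1, f2, n_iter) {
  ord <- topo_order(fam_ped)
  a1 <- matrix(0L, n_iter, length(ord), dimnames = list(NULL, ord))
  a2 <- a1
  for (id in colnames(f1)) {
    a1[, id] <- f1[, id]
    a2[, id] <- f2[, id]
  }
  for (id in ord) {
    row <- fam_ped[fam_ped$individual_id == id, ]
    if (is.na(row$father_id)) next
    pick_f <- runif(n_iter) < 0.5
    pick_m <- runif(n_iter) < 0.5
    a1[, id] <- ifelse(pick_f, a1[, row$father_id], a2[, row$father_id])
    a2[, id] <- ifelse(pick_m, a1[, row$mother_id], a2[, row$mother_id])
  }
  a1 + a2
}

#' Drop a variant through a pedigree
#'
#' Simulates Mendelian transmission of a biallelic variant conditional on
#' founder genotypes: each non-founder receives one allele drawn uniformly
#' from each parent's two alleles, independently across meioses. Founders
#' keep their assigned counts. Uses the current RNG state.
#'
#' @param fam_ped Pedigree rows of a single family.
#' @param founder_counts Named integer vector (0/1/2) covering every founder.
#' @return Named integer vector of alt counts for every family member.
#' @export
#' @examples
#' ped <- tibble::tibble(
#'   family_id = "F", individual_id = c("p1", "p2", "c1"),
#'   father_id = c(NA, NA, "p1"), mother_id = c(NA, NA, "p2"),
#'   sex = c("male", "female", "unknown"),
#'   phenotype = "unknown", penetrance_exempt = FALSE, genotyped = TRUE
#' )
#' set.seed(1)
#' gene_drop(ped, c(p1 = 1L, p2 = 0L))
gene_drop <- function(fam_ped, founder_counts) {
  founders <- founder_ids(fam_ped)
  missing_f <- setdiff(founders, names(founder_counts))
  if (length(missing_f) > 0) {
    abort_config(sprintf("founder '%s' has no assigned genotype", missing_f[1]))
  }
  fc <- founder_counts[founders]
  if (any(is.na(fc)) || any(!fc %in% 0:2)) {
    abort_config("founder genotypes must be 0, 1 or 2")
  }
  f1 <- matrix(as.integer(fc >= 1L), 1, length(founders),
    dimnames = list(NULL, founders)
  )
  f2 <- matrix(as.integer(fc == 2L), 1, length(founders),
    dimnames = list(NULL, founders)
  )
  counts <- gene_drop_core(fam_ped, f1, f2, 1L)
  setNames(as.integer(counts[1, ]), colnames(counts))
}

# Null carrier matrix for one family and one gene: n_iter x n_members logical
# (carrier of >=1 qualifying allele). Founder genotypes are held at their
# observed values; unobserved founders are hom-ref unless observed carriage
# in descendants forces a carrier founder, drawn uniformly per iteration
# among the ungenotyped founders ancestral to an observed carrier. Because a
# founder is imputed only when carriage was observed among genotyped members,
# the null draws for such a variant are conditioned on the same event (at
# least one genotyped member carries) by rejection resampling; without this
# ascertainment correction the observed statistic is stochastically larger
# than the null and the test is anti-conservative.
null_carriers_family <- function(fam_ped, genos, n_iter, max_rounds = 60L) {
  founders <- founder_ids(fam_ped)
  anc <- founder_ancestors(fam_ped)
  members <- fam_ped$individual_id
  geno_members <- members[fam_ped$genotyped]
  carrier <- matrix(FALSE, n_iter, length(members), dimnames = list(NULL, members))
  for (g in genos) {
    g_fam <- g[intersect(members, names(g))]
    obs <- g_fam[!is.na(g_fam)]
    known_f <- intersect(founders, names(obs))
    base <- setNames(rep(0L, length(founders)), founders)
    base[known_f] <- as.integer(obs[known_f])
    f1 <- matrix(rep(as.integer(base >= 1L), each = n_iter), n_iter,
      dimnames = list(NULL, founders)
    )
    f2 <- matrix(rep(as.integer(base == 2L), each = n_iter), n_iter,
      dimnames = list(NULL, founders)
    )
    obs_carriers <- names(obs)[obs >= 1L]
    forced <- FALSE
    cand <- character(0)
    if (sum(base) == 0L && length(obs_carriers) > 0) {
      unknown_f <- setdiff(founders, known_f)
      cand <- unknown_f[map_lgl(unknown_f, function(f) {
        any(map_lgl(obs_carriers, \(m) f %in% anc[[m]]))
      })]
      if (length(cand) > 0) {
        forced <- TRUE
        pick <- cand[sample.int(length(cand), n_iter, replace = TRUE)]
        f1[cbind(seq_len(n_iter), match(pick, founders))] <- 1L
      }
      # no candidate: observed carriage is Mendelian-inconsistent with the
      # genotyped founders; the family contributes its observed founders only
    }
    counts <- gene_drop_core(fam_ped, f1, f2, n_iter)
    if (forced) {
      # ascertainment correction: redraw iterations in which the imputed
      # allele reached no genotyped member
      bad <- which(rowSums(counts[, geno_members, drop = FALSE] >= 1L) == 0)
      round <- 0L
      while (length(bad) > 0 && round < max_rounds) {
        round <- round + 1L
        nb <- length(bad)
        f1b <- matrix(0L, nb, length(founders), dimnames = list(NULL, founders))
        f2b <- f1b
        pick <- cand[sample.int(length(cand), nb, replace = TRUE)]
        f1b[cbind(seq_len(nb), match(pick, founders))] <- 1L
        redo <- gene_drop_core(fam_ped, f1b, f2b, nb)
        counts[bad, ] <- redo
        ok <- rowSums(redo[, geno_members, drop = FALSE] >= 1L) > 0
        bad <- bad[!ok]
      }
    }
    carrier <- carrier | (counts[, members, drop = FALSE] >= 1L)
  }
  carrier
}

# Observed carrier ids (alt count >= 1 for any qualifying variant).
observed_carriers <- function(genos, ids) {
  keep(ids, function(m) {
    any(map_lgl(genos, function(g) {
      m %in% names(g) && !is.na(g[[m]]) && g[[m]] >= 1L
    }))
  })
}

#' Pedigree gene-burden test by gene-dropping permutation
#'
#' Tests whether a gene's qualifying rare variants are carried by affected
#' family members more than Mendelian transmission alone predicts. The
#' observed statistic is, summed over families, the number of genotyped
#' affected carriers of at least one qualifying allele minus the number of
#' genotyped non-exempt unaffected carriers; suggestive individuals
#' contribute to neither term. The null distribution re-drops non-founder
#' genotypes through each pedigree conditional on the observed founder
#' genotypes (the variant's presence in a family is taken as given, matching
#' the rare-variant setting) and the one-sided p-value is
#' `(1 + #\{S_null >= S_obs\}) / (n_iterations + 1)`, which cannot be zero.
#'
#' @param variants Variant tibble restricted to the gene's qualifying
#'   variants (conventionally every rare variant of the gene surviving
#'   [apply_rare_filters()], before segregation filtering).
#' @param ped Pedigree tibble.
#' @param gene Gene symbol (label only).
#' @param cfg A [gene_drop_config()]; the RNG is seeded from
#'   `derive_seed(cfg$seed, gene)` so a scan is order-invariant.
#' @return A one-row tibble of class `famseg_burden`: `gene`,
#'   `observed_statistic`, `p_value`, `n_iterations`, `n_families_used`,
#'   `families_used` (list-column).
#' @export
family_burden_test <- function(variants, ped, gene = "gene",
                               cfg = gene_drop_config()) {
  fams <- unique(ped$family_id)
  genos <- variants$geno
  if (length(genos) == 0) {
    out <- tibble(
      gene = gene, observed_statistic = 0L, p_value = 1,
      n_iterations = cfg$n_iterations, n_families_used = 0L,
      families_used = list(character(0))
    )
    class(out) <- c("famseg_burden", class(out))
    return(out)
  }
  n_iter <- cfg$n_iterations
  with_seed(derive_seed(cfg$seed, gene), {
    s_obs <- 0L
    s_null <- rep(0L, n_iter)
    used <- character(0)
    for (fam in fams) {
      fam_ped <- ped[ped$family_id == fam, ]
      if (!any(fam_ped$genotyped)) {
        inform(sprintf("family '%s' has no genotyped members; skipped", fam))
        next
      }
      used <- c(used, fam)
      aff <- fam_ped$individual_id[fam_ped$genotyped & fam_ped$phenotype == "affected"]
      una <- fam_ped$individual_id[
        fam_ped$genotyped & fam_ped$phenotype == "unaffected" & !fam_ped$penetrance_exempt
      ]
      obs_aff <- length(observed_carriers(genos, aff))
      obs_una <- length(observed_carriers(genos, una))
      s_obs <- s_obs + obs_aff - obs_una
      carrier <- null_carriers_family(fam_ped, genos, n_iter)
      contrib <- if (length(aff) > 0) {
        rowSums(carrier[, aff, drop = FALSE])
      } else {
        0L
      }
      if (length(una) > 0) contrib <- contrib - rowSums(carrier[, una, drop = FALSE])
      s_null <- s_null + contrib
    }
    p <- (1 + sum(s_null >= s_obs)) / (n_iter + 1)
    out <- tibble(
      gene = gene, observed_statistic = as.integer(s_obs), p_value = p,
      n_iterations = n_iter, n_families_used = length(used),
      families_used = list(used)
    )
    class(out) <- c("famseg_burden", class(out))
    out
  })
}

#' Burden tests for a set of genes
#'
#' Runs [family_burden_test()] for each gene, using each gene's qualifying
#' variant set from `variants` (rows grouped by the `gene` column). Per-gene
#' RNG streams are derived from the master seed, so the result is invariant
#' to the order of `genes`.
#'
#' @param variants Variant tibble (post rare-filter) with a `gene` column.
#' @param ped Pedigree tibble.
#' @param genes Genes to test; default every annotated gene in `variants`.
#' @param cfg A [gene_drop_config()].
#' @return A tibble of class `famseg_burden`, one row per gene, sorted by
#'   gene.
#' @export
burden_scan <- function(variants, ped, genes = NULL, cfg = gene_drop_config()) {
  genes <- sort(genes %||% unique(stats::na.omit(variants$gene)))
  rows <- map(genes, function(g) {
    family_burden_test(variants[!is.na(variants$gene) & variants$gene == g, ],
      ped,
      gene = g, cfg = cfg
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("famseg_burden", class(out))
  out
}
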