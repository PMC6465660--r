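#' Controlled vocabularies
#'
#' Phenotype states, effect classes and the default population allele
#' frequency sources recognised across the package.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
phenotype_levels <- c("affected", "suggestive", "unaffected", "unknown")

#' @rdname vocabularies
#' @export
effect_classes <- c(
  "frameshift_indel", "nonframeshift_indel", "nonsynonymous",
  "stopgain", "stoploss", "unknown_effect", "splicing",
  "synonymous", "other"
)

#' @rdname vocabularies
#' @export
default_af_sources <- c(
  "1000g_all", "1000g_eur", "exac_all", "exac_nfe", "exac_fin", "esp6500_all"
)

# Adult-onset actionable genes removed to avoid secondary findings.
acmg_adult_onset_genes <- c(
  "BRCA1", "BRCA2", "MLH1", "MSH2", "MSH6", "PMS2", "MUTYH"
)

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

abort_format <- function(msg, ...) {
  abort(msg, class = "famseg_format_error", ...)
}

abort_consistency <- function(msg, ...) {
  abort(msg, class = "famseg_consistency_error", ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = "famseg_config_error", ...)
}

abort_domain <- function(msg, ...) {
  abort(msg, class = "famseg_domain_error", ...)
}

# 32-bit FNV-1a hash of a string, returned in [0, 2^31).  Used to derive
# stable per-gene RNG streams from a single master seed so that burden
# results do not depend on gene evaluation order.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte (b < 256); h may exceed .Machine$integer.max
    low8 <- h %% 256
    h <- h - low8 + bitwXor(low8, b %% 256)
    # multiply by the FNV prime modulo 2^32 in 16-bit limbs (doubles cannot
    # hold the full 32x24-bit product exactly)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483648
}

derive_seed <- function(master_seed, label) {
  as.integer((as.numeric(master_seed) + fnv1a32(label)) %% 2147483647L)
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# FNV-1a hash of a deparsed object; used for the run-report config hash.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  sprintf("%08x", fnv1a32(txt))
}

order_variants <- function(df) {
  arrange(df, .data$chrom, .data$pos, .data$alt)
}
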