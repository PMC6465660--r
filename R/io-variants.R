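#' Read raw sites from a multi-sample VCF
#'
#' Reads the fixed fields and GT calls of a VCF (v4.x) into a tibble of raw,
#' possibly multiallelic sites. Only the GT subfield is used; genotype
#' likelihoods and INFO annotations are out of scope (annotations come from a
#' separate table, see [read_annotation()]).
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @return A tibble with columns `chrom`, `pos` (1-based), `rsid` (`NA` when
#'   missing), `ref`, `alt` (comma-separated when multiallelic) and `gt`, a
#'   list-column of named character GT strings per sample. The VCF sample ids
#'   are attached as attribute `"samples"`.
#' @export
read_vcf <- function(path) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort_format(paste("cannot parse VCF:", conditionMessage(e)))
  )
  if (nrow(v@fix) == 0) abort_format("VCF contains no variant records")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  sites <- tibble(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    rsid = ifelse(fix[, "ID"] %in% c(".", NA), NA_character_, fix[, "ID"]),
    ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"]),
    gt = map(seq_len(nrow(gt)), \(i) setNames(gt[i, ], samples))
  )
  attr(sites, "samples") <- samples
  sites
}

# Parse one GT string into a vector of allele indices, or NULL for missing.
# A genotype with any missing allele ("./.", "0/.") is treated as missing;
# how missing genotypes enter each rule is owned by the downstream modules.
parse_gt <- function(gt, n_alt, where = "") {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NULL)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NULL)
  if (!all(grepl("^[0-9]+$", alleles))) {
    abort_format(sprintf("malformed GT '%s'%s", gt, where))
  }
  idx <- as.integer(alleles)
  if (any(idx > n_alt)) {
    abort_consistency(sprintf(
      "GT '%s'%s references allele %d but site has %d alt allele(s)",
      gt, where, max(idx), n_alt
    ))
  }
  idx
}

#' Read a variant annotation table
#'
#' Annotations are consumed, not produced: the table is the output of an
#' external annotator, keyed by `(chrom, pos, ref, alt)`, with a mandatory
#' header. Population allele frequency columns are prefixed `af_` (one per
#' source, e.g. `af_1000g_all`); `control_maf` is the in-cohort control minor
#' allele frequency and `cadd_phred` the scaled CADD deleteriousness score.
#'
#' @param path Path to a tab-separated annotation file.
#' @return A tibble with one row per annotated variant; a duplicated
#'   `(chrom, pos, ref, alt)` key is a consistency error.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character(), gene = readr::col_character(),
      effect = readr::col_character(), .default = readr::col_guess()
    )
  )
  required <- c("chrom", "pos", "ref", "alt", "gene", "effect")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("annotation table lacks column '%s'", missing_cols[1]))
  }
  ann$chrom <- as.character(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  bad_eff <- setdiff(stats::na.omit(unique(ann$effect)), effect_classes)
  if (length(bad_eff) > 0) {
    abort_format(sprintf("unknown effect class '%s'", bad_eff[1]))
  }
  dup <- ann |> count(.data$chrom, .data$pos, .data$ref, .data$alt) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_consistency(sprintf(
      "duplicate annotation key %s", variant_key(dup$chrom[1], dup$pos[1], dup$ref[1], dup$alt[1])
    ))
  }
  if (!"control_maf" %in% names(ann)) ann$control_maf <- NA_real_
  if (!"cadd_phred" %in% names(ann)) ann$cadd_phred <- NA_real_
  af_cols <- grep("^af_", names(ann), value = TRUE)
  for (col in c(af_cols, "control_maf")) {
    out_of_range <- !is.na(ann[[col]]) & (ann[[col]] < 0 | ann[[col]] > 1)
    if (any(out_of_range)) {
      abort_domain(sprintf("column '%s' has a frequency outside [0, 1]", col))
    }
  }
  if (any(!is.na(ann$cadd_phred) & ann$cadd_phred < 0)) {
    abort_domain("cadd_phred must be non-negative")
  }
  ann
}

#' Read low-complexity (or other excluded) regions from a BED3 file
#'
#' BED coordinates are 0-based half-open and are kept that way internally;
#' the conversion to the VCF's 1-based positions happens in the containment
#' test ([in_regions()]). Intervals are sorted and merged on read.
#'
#' @param path Path to a BED3 file (no header; track lines ignored).
#' @return A tibble `chrom`, `start`, `end` of sorted, merged, half-open
#'   intervals.
#' @export
read_bed_regions <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- str_split(trimws(lines), "\\s+")
  if (any(lengths(fields) < 3)) abort_format("BED line with fewer than 3 fields")
  bed <- tibble(
    chrom = map_chr(fields, 1),
    start = as.integer(map_chr(fields, 2)),
    end = as.integer(map_chr(fields, 3))
  )
  if (any(is.na(bed$start) | is.na(bed$end))) abort_format("non-numeric BED coordinates")
  if (any(bed$start >= bed$end)) abort_format("BED interval with start >= end")
  merge_regions(bed)
}

# Sort and merge half-open intervals per chromosome (IRanges::reduce).
merge_regions <- function(bed) {
  bed |>
    group_by(.data$chrom) |>
    group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1L, end = df$end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start)
}

#' Test whether 1-based positions fall in a region set
#'
#' @param chrom,pos Parallel vectors of chromosome and 1-based position.
#' @param regions Region tibble from [read_bed_regions()].
#' @return Logical vector.
#' @export
in_regions <- function(chrom, pos, regions) {
  out <- logical(length(pos))
  for (cc in unique(chrom)) {
    reg <- regions[regions$chrom == cc, ]
    sel <- chrom == cc
    if (nrow(reg) == 0) next
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    s <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    out[sel] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Read and join a VCF with its annotation table
#'
#' Reads the VCF, decomposes multiallelic sites into biallelic records (see
#' [decompose_multiallelic()]) and left-joins the annotation table on
#' `(chrom, pos, ref, alt)`. Variants without an annotation row are retained
#' with all-missing annotation fields; missing genotypes are recorded as `NA`
#' alt counts, never as 0.
#'
#' @param vcf_path Path to the VCF.
#' @param annotation_path Path to the annotation table, or `NULL` to attach
#'   all-missing annotations.
#' @param af_sources Population frequency sources expected as `af_<source>`
#'   columns; absent columns are created as missing.
#' @return A variant tibble: `chrom`, `pos`, `ref`, `alt`, `rsid`,
#'   `variant_id`, `geno` (list-column of named integer alt counts per sample,
#'   `NA` = missing), `gene`, `effect`, `af_*`, `control_maf`, `cadd_phred`,
#'   `is_indel`. VCF samples attached as attribute `"samples"`.
#' @export
parse_variant_table <- function(vcf_path, annotation_path, af_sources = default_af_sources) {
  sites <- read_vcf(vcf_path)
  samples <- attr(sites, "samples")
  variants <- decompose_multiallelic(sites)
  if (!is.null(annotation_path)) {
    ann <- read_annotation(annotation_path)
    variants <- left_join(variants, ann, by = c("chrom", "pos", "ref", "alt"))
  }
  for (col in c(paste0("af_", af_sources), "control_maf", "cadd_phred")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  }
  if (!"gene" %in% names(variants)) variants$gene <- NA_character_
  if (!"effect" %in% names(variants)) variants$effect <- NA_character_
  variants$is_indel <- nchar(variants$ref) != nchar(variants$alt)
  attr(variants, "samples") <- samples
  variants
}

#' Write a variant tibble as a GT-only VCF v4.2 file
#'
#' Emits biallelic records with a single GT FORMAT field; alt counts 0/1/2 map
#' to `0/0`, `0/1`, `1/1` and missing to `./.`. Used by the synthetic-data
#' generator and for round-trip checks.
#'
#' @param variants Variant tibble with a `geno` list-column.
#' @param path Output path.
#' @param samples Sample order; defaults to the names of the first genotype
#'   vector.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, samples = NULL) {
  samples <- samples %||% names(variants$geno[[1]])
  gt_of <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
      collapse = "\t"
    )
  )
  body <- pmap(
    list(variants$chrom, variants$pos, variants$rsid, variants$ref,
         variants$alt, variants$geno),
    function(chrom, pos, rsid, ref, alt, geno) {
      counts <- geno[samples]
      gts <- ifelse(is.na(counts), "./.", gt_of[as.character(counts)])
      paste(c(chrom, pos, ifelse(is.na(rsid), ".", rsid), ref, alt, ".", "PASS", ".",
              "GT", gts), collapse = "\t")
    }
  )
  readr::write_lines(c(header, unlist(body)), path)
  invisible(path)
}

#' Write an annotation table
#'
#' @param ann Annotation tibble (as read by [read_annotation()], or the
#'   annotation columns of a variant tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  keep_cols <- c(
    "chrom", "pos", "ref", "alt", "gene", "effect",
    grep("^af_", names(ann), value = TRUE), "control_maf", "cadd_phred"
  )
  readr::write_tsv(ann[, intersect(keep_cols, names(ann))], path, progress = FALSE)
  invisible(path)
}

#' Write a region tibble as BED3
#'
#' @param regions Region tibble (`chrom`, `start`, `end`; 0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(regions, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
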