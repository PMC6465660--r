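#' Pipeline run configuration
#'
#' Collects the file paths, filter thresholds, burden settings and stage
#' toggles of a full pipeline run. Can be built in R or loaded from a YAML
#' file with [read_run_config()].
#'
#' @param vcf,ped,annotation,lcr Paths to the input files (`lcr` and
#'   `annotation` may be `NULL`).
#' @param out_dir Output directory for report files.
#' @param exempt Penetrance-exempt individual ids, or a path to a text file
#'   with one id per line.
#' @param filter A [filter_config()].
#' @param burden A [gene_drop_config()].
#' @param run_burden Toggle for the gene-burden stage.
#' @return A list of class `famseg_run_config`.
#' @export
run_config <- function(vcf, ped, annotation = NULL, lcr = NULL,
                       out_dir = tempfile("famseg_run"),
                       exempt = character(),
                       filter = filter_config(),
                       burden = gene_drop_config(),
                       run_burden = TRUE) {
  for (p in c(vcf, ped, annotation, lcr)) {
    if (!file.exists(p)) abort_config(sprintf("input file '%s' does not exist", p))
  }
  if (length(exempt) == 1 && file.exists(exempt)) {
    exempt <- readr::read_lines(exempt)
    exempt <- exempt[nzchar(trimws(exempt))]
  }
  structure(
    list(
      vcf = vcf, ped = ped, annotation = annotation, lcr = lcr,
      out_dir = out_dir, exempt = exempt, filter = filter, burden = burden,
      run_burden = run_burden
    ),
    class = "famseg_run_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys: `vcf`, `ped`, `annotation`, `lcr`, `out_dir`, `exempt`
#' (list or file path), `run_burden`, and nested `filter` / `burden` blocks
#' whose entries override the [filter_config()] / [gene_drop_config()]
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `famseg_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fc <- do.call(filter_config, y$filter %||% list())
  bc <- do.call(gene_drop_config, y$burden %||% list())
  run_config(
    vcf = y$vcf, ped = y$ped, annotation = y$annotation, lcr = y$lcr,
    out_dir = y$out_dir %||% tempfile("famseg_run"),
    exempt = unlist(y$exempt) %||% character(),
    filter = fc, burden = bc,
    run_burden = y$run_burden %||% TRUE
  )
}

#' Run the full family rare-variant pipeline
#'
#' Executes, in order: input parsing and sample reconciliation (a VCF/PED
#' sample mismatch is fatal before any filtering), dataset preparation
#' ([qc_prefilter()]), the rare-variant cascade ([apply_rare_filters()]),
#' global unaffected-carrier removal, per-family segregation, cross-family
#' aggregation, and (optionally) the gene-dropping burden test for genes with
#' multiple segregating variants in two or more families — each burden test
#' using all of that gene's post-cascade rare variants. Report tables, filter
#' tallies and a machine-readable run report (config hash, seed, per-stage
#' variant counts) are written to `cfg$out_dir`.
#'
#' @param cfg A [run_config()] or path to a YAML configuration.
#' @return Invisibly, a list with every intermediate result: `ped`,
#'   `variants` (post-QC), `filtered`, `carrier_filtered`, `segregation`,
#'   `shared`, `multi_gene`, `within_family`, `summary`, `burden`, `report`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  ped <- read_pedigree(cfg$ped, exempt = cfg$exempt)
  variants <- parse_variant_table(cfg$vcf, cfg$annotation,
    af_sources = cfg$filter$af_sources
  )
  samples <- attr(variants, "samples")
  ped <- align_samples(ped, samples)
  n_input <- nrow(variants)

  lcr <- if (!is.null(cfg$lcr)) {
    read_bed_regions(cfg$lcr)
  } else {
    tibble(chrom = character(), start = integer(), end = integer())
  }
  prepped <- qc_prefilter(variants, lcr,
    family_samples = samples,
    hwe_threshold = cfg$filter$hwe_threshold
  )
  filtered <- apply_rare_filters(prepped, cfg$filter)
  carrier_filtered <- remove_global_unaffected_carriers(filtered, ped)
  segregation <- segregating_variants(carrier_filtered, ped)
  shared <- shared_variants(segregation)
  multi_gene <- multi_variant_genes(segregation)
  within_family <- within_family_multihit(segregation)
  counts <- family_counts(segregation, ped)
  summary <- cohort_summary(counts)

  burden <- NULL
  if (cfg$run_burden && nrow(multi_gene) > 0) {
    burden <- burden_scan(filtered, ped, genes = multi_gene$gene, cfg = cfg$burden)
  }

  report <- list(
    config_hash = config_hash(cfg[setdiff(names(cfg), "out_dir")]),
    seed = cfg$burden$seed,
    stage_counts = list(
      input = n_input,
      post_qc = nrow(prepped),
      post_rare_filter = nrow(filtered),
      post_unaffected_carrier = nrow(carrier_filtered),
      segregating_pairs = nrow(segregation),
      shared_variants = nrow(shared),
      multi_variant_genes = nrow(multi_gene)
    ),
    qc_tally = as.list(attr(prepped, "tally")),
    filter_tally = as.list(attr(filtered, "tally"))
  )

  write_reports(cfg$out_dir, counts, shared, multi_gene, segregation,
    decisions = attr(filtered, "decisions"), burden = burden, report = report
  )
  inform(sprintf(
    "pipeline: %d variants in, %d post-QC, %d post-filter, %d post-carrier-removal; %d shared variants, %d multi-variant genes",
    n_input, nrow(prepped), nrow(filtered), nrow(carrier_filtered),
    nrow(shared), nrow(multi_gene)
  ))
  invisible(list(
    ped = ped, variants = prepped, filtered = filtered,
    carrier_filtered = carrier_filtered, segregation = segregation,
    shared = shared, multi_gene = multi_gene, within_family = within_family,
    summary = summary, burden = burden, report = report
  ))
}

# Tab-separated report tables mirroring the overview / shared-variant /
# multi-variant-gene layouts, plus per-family segregating-variant lists,
# the per-variant filter decisions and the JSON run report.
write_reports <- function(out_dir, counts, shared, multi_gene, segregation,
                          decisions, burden, report) {
  readr::write_tsv(
    counts |> rename(
      family = "family_id", affected = "n_affected", suggestive = "n_suggestive",
      unaffected = "n_unaffected", segregating_variants = "n_segregating"
    ),
    file.path(out_dir, "family_overview.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    shared |> mutate(families = map_chr(.data$families, paste, collapse = ",")),
    file.path(out_dir, "shared_variants.tsv"),
    progress = FALSE
  )
  readr::write_tsv(
    multi_gene |> mutate(
      families = map_chr(.data$families, paste, collapse = ","),
      variant_ids = map_chr(.data$variant_ids, paste, collapse = ",")
    ),
    file.path(out_dir, "multi_variant_genes.tsv"),
    progress = FALSE
  )
  readr::write_tsv(segregation, file.path(out_dir, "segregating_variants.tsv"),
    progress = FALSE
  )
  readr::write_tsv(decisions, file.path(out_dir, "filter_decisions.tsv"),
    progress = FALSE
  )
  if (!is.null(burden)) {
    readr::write_tsv(
      as_tibble(burden) |> select(-"families_used"),
      file.path(out_dir, "burden_results.tsv"),
      progress = FALSE
    )
  }
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(out_dir)
}
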