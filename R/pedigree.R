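#' Read a pedigree file
#'
#' Parses a 6-column whitespace-delimited pedigree (PED) file into a tidy
#' pedigree tibble, one row per individual. The phenotype column uses an
#' extended dialect with a third affection state for individuals whose
#' clinical picture is suggestive of, but not diagnostic for, the disease:
#' `1` = unaffected, `2` = affected, `3` = suggestive, `0`/`-9` = unknown.
#'
#' Penetrance exemptions generalise the case of an unaffected obligate
#' carrier in a reduced-penetrance family: exempt individuals are skipped by
#' every "absent in unaffected" constraint downstream. They are supplied as a
#' list of individual ids (optionally qualified as `"family:individual"`),
#' not hard-coded.
#'
#' @param path Path to a PED file.
#' @param exempt Character vector of penetrance-exempt individual ids, either
#'   bare ids or `"family_id:individual_id"`.
#' @return A tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (`NA` for founders), `sex` (`male`/`female`/`unknown`),
#'   `phenotype` (`affected`/`suggestive`/`unaffected`/`unknown`),
#'   `penetrance_exempt`, `genotyped` (initially `TRUE`; reconciled against
#'   the VCF sample set by [align_samples()]).
#' @seealso [write_ped()], [align_samples()]
#' @export
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("FAM1 I1 0 0 1 1", "FAM1 I2 0 0 2 3", "FAM1 II1 I1 I2 1 2"), ped)
#' read_pedigree(ped)
read_pedigree <- function(path, exempt = character()) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) abort_format("pedigree file has no records")
  fields <- str_split(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 6L)
  if (length(bad) > 0) {
    abort_format(sprintf(
      "pedigree line %d has %d fields (6 expected)", bad[1], length(fields[[bad[1]]])
    ))
  }
  m <- do.call(rbind, fields)
  pheno_code <- m[, 6]
  known <- c("1", "2", "3", "0", "-9")
  if (!all(pheno_code %in% known)) {
    bad_code <- setdiff(unique(pheno_code), known)[1]
    abort_format(sprintf("unknown phenotype code '%s'", bad_code))
  }
  ped <- tibble(
    family_id = m[, 1],
    individual_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = dplyr::case_match(m[, 5], "1" ~ "male", "2" ~ "female", .default = "unknown"),
    phenotype = dplyr::case_match(
      pheno_code,
      "1" ~ "unaffected", "2" ~ "affected", "3" ~ "suggestive",
      .default = "unknown"
    ),
    penetrance_exempt = FALSE,
    genotyped = TRUE
  )
  dup <- ped |> count(.data$family_id, .data$individual_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort_consistency(sprintf(
      "duplicate individual '%s' in family '%s'",
      dup$individual_id[1], dup$family_id[1]
    ))
  }
  ped$penetrance_exempt <- ped$individual_id %in% exempt |
    paste(ped$family_id, ped$individual_id, sep = ":") %in% exempt
  bad_exempt <- ped$penetrance_exempt & ped$phenotype != "unaffected"
  if (any(bad_exempt)) {
    abort_consistency(sprintf(
      "penetrance-exempt individual '%s' is not unaffected",
      ped$individual_id[which(bad_exempt)[1]]
    ))
  }
  missing_exempt <- setdiff(
    exempt,
    c(ped$individual_id, paste(ped$family_id, ped$individual_id, sep = ":"))
  )
  if (length(missing_exempt) > 0) {
    abort_consistency(sprintf(
      "exemption list names unknown individual '%s'", missing_exempt[1]
    ))
  }
  validate_pedigree(ped)
}

#' Validate a pedigree tibble
#'
#' Checks parent links (both absent or both resolving to members of the same
#' family), acyclicity, and uniqueness of individual ids within families.
#' Returns the input invisibly unchanged on success so it can sit inside a
#' pipe.
#'
#' @param ped A pedigree tibble as returned by [read_pedigree()].
#' @return `ped`, invisibly validated.
#' @export
validate_pedigree <- function(ped) {
  one_parent <- is.na(ped$father_id) != is.na(ped$mother_id)
  if (any(one_parent)) {
    abort_consistency(sprintf(
      "individual '%s' has exactly one parent recorded; founders must have none",
      ped$individual_id[which(one_parent)[1]]
    ))
  }
  for (fam in unique(ped$family_id)) {
    sub <- ped[ped$family_id == fam, ]
    parents <- stats::na.omit(c(sub$father_id, sub$mother_id))
    undefined <- setdiff(parents, sub$individual_id)
    if (length(undefined) > 0) {
      abort_consistency(sprintf(
        "family '%s': parent '%s' referenced but never defined", fam, undefined[1]
      ))
    }
    # acyclicity via topological elimination
    remaining <- sub
    repeat {
      founder_like <- is.na(remaining$father_id) |
        !(remaining$father_id %in% remaining$individual_id)
      founder_like <- founder_like &
        (is.na(remaining$mother_id) |
          !(remaining$mother_id %in% remaining$individual_id))
      if (all(founder_like)) break
      if (!any(founder_like)) {
        abort_consistency(sprintf("family '%s': pedigree contains a cycle", fam))
      }
      remaining <- remaining[!founder_like, , drop = FALSE]
      if (nrow(remaining) == 0) break
    }
  }
  ped
}

#' Write a pedigree tibble to a PED file
#'
#' Inverse of [read_pedigree()]; re-parsing the written file reproduces the
#' parsed columns (the `penetrance_exempt` and `genotyped` flags live outside
#' the PED format).
#'
#' @param ped Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  code <- dplyr::case_match(
    ped$phenotype,
    "unaffected" ~ "1", "affected" ~ "2", "suggestive" ~ "3", .default = "0"
  )
  sex <- dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2", .default = "0")
  lines <- paste(
    ped$family_id, ped$individual_id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex, code
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Reconcile pedigree and VCF sample sets
#'
#' Every sample in the VCF must match exactly one pedigree individual; this is
#' enforced before any filtering so that genotype-dependent rules never run on
#' an inconsistent cohort. Pedigree members absent from the VCF (e.g. a family
#' member who declined sequencing) are legal and get `genotyped = FALSE`;
#' genotype-dependent rules ignore them.
#'
#' @param ped Pedigree tibble.
#' @param samples Character vector of VCF sample ids.
#' @return `ped` with the `genotyped` column set from the sample list.
#' @export
align_samples <- function(ped, samples) {
  hits <- map_int(samples, \(s) sum(ped$individual_id == s))
  if (any(hits == 0)) {
    abort_consistency(sprintf(
      "VCF sample '%s' does not appear in any pedigree", samples[which(hits == 0)[1]]
    ))
  }
  if (any(hits > 1)) {
    abort_consistency(sprintf(
      "VCF sample '%s' matches more than one pedigree individual",
      samples[which(hits > 1)[1]]
    ))
  }
  ped$genotyped <- ped$individual_id %in% samples
  ped
}

# Founders of one family sub-pedigree.
founder_ids <- function(fam_ped) {
  fam_ped$individual_id[is.na(fam_ped$father_id)]
}

# Members in an order where parents precede children.
topo_order <- function(fam_ped) {
  ids <- fam_ped$individual_id
  placed <- character(0)
  pending <- ids
  while (length(pending) > 0) {
    ready <- map_lgl(pending, function(id) {
      row <- fam_ped[fam_ped$individual_id == id, ]
      (is.na(row$father_id) || row$father_id %in% placed) &&
        (is.na(row$mother_id) || row$mother_id %in% placed)
    })
    if (!any(ready)) abort_consistency("pedigree contains a cycle")
    placed <- c(placed, pending[ready])
    pending <- pending[!ready]
  }
  placed
}
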