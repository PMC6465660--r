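#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an allelic association result
#'
#' @param x A `famseg_assoc` from [allelic_odds_ratio()].
#' @param ... Unused.
#' @return A one-row tibble: `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `corrected`.
#' @method tidy famseg_assoc
#' @export
tidy.famseg_assoc <- function(x, ...) {
  tibble(
    odds_ratio = x$odds_ratio, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, corrected = x$corrected
  )
}

#' @rdname tidy.famseg_assoc
#' @method glance famseg_assoc
#' @export
glance.famseg_assoc <- function(x, ...) {
  tidy(x) |> mutate(n_alleles = sum(x$counts))
}

#' Tidy burden-test results
#'
#' `tidy()` returns the per-gene table (family lists flattened to
#' comma-separated strings); `glance()` one row summarising the scan.
#'
#' @param x A `famseg_burden` from [family_burden_test()] or [burden_scan()].
#' @param ... Unused.
#' @method tidy famseg_burden
#' @export
tidy.famseg_burden <- function(x, ...) {
  as_tibble(x) |>
    mutate(families_used = map_chr(.data$families_used, paste, collapse = ","))
}

#' @rdname tidy.famseg_burden
#' @method glance famseg_burden
#' @export
glance.famseg_burden <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_iterations = max(x$n_iterations),
    min_p = min(x$p_value),
    n_nominal = sum(x$p_value <= 0.05)
  )
}

#' Tidy a cohort summary
#'
#' `tidy()` returns the per-family counts; `glance()` the cohort-level
#' scalars (family count, phenotype totals, mean/min/max segregating
#' variants).
#'
#' @param x A `famseg_cohort_summary` from [cohort_summary()].
#' @param ... Unused.
#' @method tidy famseg_cohort_summary
#' @export
tidy.famseg_cohort_summary <- function(x, ...) {
  as_tibble(x$per_family)
}

#' @rdname tidy.famseg_cohort_summary
#' @method glance famseg_cohort_summary
#' @export
glance.famseg_cohort_summary <- function(x, ...) {
  as_tibble(x[setdiff(names(x), "per_family")])
}
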