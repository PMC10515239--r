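# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn pav_scan `tidy()` returns the retained PAV segments.
#' @param x A `pav_result`.
#' @param ... Unused.
#' @export
tidy.pav_result <- function(x, ...) x$segments

#' @describeIn pav_scan `glance()` returns the per-genome summary report.
#' @export
glance.pav_result <- function(x, ...) x$report

#' @describeIn ks_distribution_peaks `tidy()` returns the modes (tallest
#'   first).
#' @param x A `ks_peaks` object.
#' @param ... Unused.
#' @export
tidy.ks_peaks <- function(x, ...) x$peaks

#' @describeIn ks_distribution_peaks `glance()` returns a one-row summary.
#' @export
glance.ks_peaks <- function(x, ...) {
  tibble(n = x$n, bandwidth = x$bandwidth, n_modes = nrow(x$peaks),
         top_mode = if (nrow(x$peaks)) x$peaks$mode[1] else NA_real_)
}

#' @describeIn call_block_variants `tidy()` returns the variant table.
#' @param x A `variant_calls` object.
#' @param ... Unused.
#' @export
tidy.variant_calls <- function(x, ...) x$variants

#' @describeIn call_block_variants `glance()` returns counts and per-kb
#'   densities.
#' @export
glance.variant_calls <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_snps = x$n_snps, n_indels = x$n_indels,
           n_excluded = x$n_excluded),
    variant_density(x))
}

#' @describeIn taxon_presence_matrix `tidy()` returns the long cell table.
#' @param x A `taxon_presence` object.
#' @param ... Unused.
#' @export
tidy.taxon_presence <- function(x, ...) x$cells

#' @describeIn taxon_presence_matrix `glance()` returns the summary row.
#' @export
glance.taxon_presence <- function(x, ...) x$summary
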