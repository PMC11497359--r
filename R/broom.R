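#' Tidy a Mann-Whitney test result
#'
#' @param x An `mwu_test`.
#' @param ... Unused.
#' @return A one-row tibble with `u_a`, `u_b`, `statistic`, `p.value` and
#'   `method`.
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble::tibble(
    u_a = x$u_a, u_b = x$u_b, statistic = x$statistic,
    p.value = x$p_value, method = x$method
  )
}

#' @rdname tidy.mwu_test
#' @export
glance.mwu_test <- function(x, ...) {
  tibble::tibble(n_a = x$n_a, n_b = x$n_b, exact = x$exact,
                 p.value = x$p_value)
}

#' Tidy a contact series
#'
#' `tidy()` returns the per-residue average contact numbers; `glance()` a
#' one-row summary with the analysis parameters and the across-residue mean.
#'
#' @param x A `contact_series`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.contact_series <- function(x, ...) {
  x$averages
}

#' @rdname tidy.contact_series
#' @export
glance.contact_series <- function(x, ...) {
  tibble::tibble(
    n_residues = dplyr::n_distinct(paste(x$averages$chain, x$averages$residue_id)),
    n_species = length(x$copies),
    n_grid_frames = length(x$params$grid_times_ps),
    cutoff_nm = x$params$cutoff_nm,
    interval_ps = x$params$interval_ps,
    equilibration_ps = x$params$equilibration_ps,
    mean_avg_contacts = mean(x$averages$avg_contacts)
  )
}
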