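#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a binned correlation result
#'
#' @param x A `ci_corr` object.
#' @param ... Unused.
#' @return One-row tibble with `label`, `estimate`, `p.value`, `n`.
#' @export
tidy.ci_corr <- function(x, ...) {
  tibble::tibble(label = x$label, estimate = x$r, p.value = x$p, n = x$n)
}

#' @rdname tidy.ci_corr
#' @export
glance.ci_corr <- function(x, ...) tidy(x)

#' Tidy a coverage enrichment test
#'
#' @param x A `ci_enrichtest` object.
#' @param ... Unused.
#' @return One-row tibble with the trial counts, null rate and both p-values.
#' @export
tidy.ci_enrichtest <- function(x, ...) {
  tibble::tibble(
    n_windows = x$n_windows, k_above_background = x$k_above_background,
    background_p0 = x$background_p0, p.value = x$p_value,
    p.permutation = x$p_permutation,
    observed_mean = x$observed_mean, background_mean = x$background_mean
  )
}

#' @rdname tidy.ci_enrichtest
#' @export
glance.ci_enrichtest <- function(x, ...) tidy(x)
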