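# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ANOVA result
#' @param x An `anova_result`. @param ... Unused.
#' @return One row per model term: `term`, `sumsq`, `df`, `statistic`,
#'   `p_value`.
#' @export
tidy.anova_result <- function(x, ...) x$table

#' @rdname tidy.anova_result
#' @export
glance.anova_result <- function(x, ...) {
  tibble::tibble(residual_df = x$residual_df, residual_ss = x$residual_ss,
                 n = nrow(x$data), n_terms = nrow(x$table))
}

#' Tidy Tukey HSD contrasts
#' @param x A `tukey_result`. @param ... Unused.
#' @export
tidy.tukey_result <- function(x, ...) x$contrasts

#' Tidy a size-transition result
#' @param x A `size_threshold`. @param ... Unused.
#' @return A one-row tibble: `n`, `threshold_um2`, `peak`, `peak_index`,
#'   `mean_derivative`, `peak_ratio`, `transition_detected`.
#' @export
tidy.size_threshold <- function(x, ...) {
  tibble::tibble(n = x$n, threshold_um2 = x$threshold_um2, peak = x$peak,
                 peak_index = x$peak_index %||% NA_integer_,
                 mean_derivative = x$mean_derivative,
                 peak_ratio = x$peak_ratio,
                 transition_detected = !is.na(x$threshold_um2))
}

#' @rdname tidy.size_threshold
#' @export
glance.size_threshold <- function(x, ...) tidy.size_threshold(x)

#' Tidy a proportion table (per-category summary)
#' @param x A `proportion_table`. @param ... Unused.
#' @export
tidy.proportion_table <- function(x, ...) x$summary

#' Tidy a nucleator measurement
#' @param x A `nucleator_measurement`. @param ... Unused.
#' @export
tidy.nucleator_measurement <- function(x, ...) {
  tibble::tibble(r_mean_um = x$r_mean_um, area_um2 = x$area_um2,
                 n_rays = length(x$radii_um),
                 center_inside = x$center_inside,
                 start_angle = x$start_angle)
}
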