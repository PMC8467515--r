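# broom-style tidiers for the package's fitted/estimated objects.

#' Tidy a C-doRNA/doRNA ratio estimate
#'
#' @param x A [estimate_ratio()] object.
#' @param ... Unused.
#' @return A one-row tibble: `c_count`, `d_count`, `estimate`,
#'   `conf_low`, `conf_high`.
#' @method tidy dorna_ratio
#' @export
tidy.dorna_ratio <- function(x, ...) {
  tibble(c_count = x$c_count, d_count = x$d_count, estimate = x$ratio,
         conf_low = x$ci_low, conf_high = x$ci_high)
}

#' @rdname tidy.dorna_ratio
#' @method glance dorna_ratio
#' @export
glance.dorna_ratio <- function(x, ...) {
  tibble(estimate = x$ratio, conf_low = x$ci_low, conf_high = x$ci_high,
         n_bootstrap = x$n_bootstrap, conf_level = x$conf_level,
         seed = x$seed %||% NA_integer_)
}

#' Tidy a ratio comparison
#'
#' @param x A [compare_ratios()] object.
#' @param ... Unused.
#' @return A one-row tibble with the log-ratio difference, its interval
#'   and the bootstrap p-value.
#' @method tidy dorna_ratio_comparison
#' @export
tidy.dorna_ratio_comparison <- function(x, ...) {
  tibble(estimate = x$log_ratio_diff, conf_low = x$ci_low,
         conf_high = x$ci_high, p_value = x$p_value,
         n_bootstrap = x$n_bootstrap)
}

#' Tidy a qPCR standard curve
#'
#' @param x A [fit_standard_curve()] object.
#' @param ... Unused.
#' @return `tidy()`: the term-level coefficients of the underlying OLS
#'   fit. `glance()`: one row with `slope`, `intercept`, `r_squared`,
#'   `efficiency` and `n`.
#' @method tidy dorna_stdcurve
#' @export
tidy.dorna_stdcurve <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = rownames(co), estimate = co[, 1], std_error = co[, 2])
}

#' @rdname tidy.dorna_stdcurve
#' @method glance dorna_stdcurve
#' @export
glance.dorna_stdcurve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         efficiency = x$efficiency, n = x$n)
}

#' Tidy a Venn partition
#'
#' @param x A [venn_partition()] object.
#' @param ... Unused.
#' @return `tidy()`: one row per region with its size and member ids.
#'   `glance()`: one row with `a_only`, `b_only`, `shared` and `union`
#'   counts.
#' @method tidy dorna_venn
#' @export
tidy.dorna_venn <- function(x, ...) {
  tibble(
    region = c(paste0(x$names[1], "_only"), "shared",
               paste0(x$names[2], "_only")),
    n = c(length(x$a_only), length(x$shared), length(x$b_only)),
    protein_ids = list(x$a_only, x$shared, x$b_only)
  )
}

#' @rdname tidy.dorna_venn
#' @method glance dorna_venn
#' @export
glance.dorna_venn <- function(x, ...) {
  tibble(a_only = length(x$a_only), b_only = length(x$b_only),
         shared = length(x$shared),
         union = length(x$a_only) + length(x$b_only) + length(x$shared))
}
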