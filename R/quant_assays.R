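# Exactly-specified quantitation computations: qPCR standard curves and
# absolute copy numbers, subcellular compartment fractions, dual-luciferase
# reporter normalization and scratch-assay wound closure.

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies) over a serial dilution.
#' Amplification efficiency is derived as `10^(-1/slope) - 1` (1.0 means
#' perfect doubling per cycle; the corresponding slope is -3.3219).
#'
#' @param dilutions A data frame with columns `copies` (> 0) and `cq`;
#'   at least 3 points, ideally spanning >= 2 orders of magnitude (a
#'   narrower span only triggers a warning).
#' @return An object of class `dorna_stdcurve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n` and the underlying `fit`;
#'   see [tidy()] / [glance()].
#' @export
#' @examples
#' d <- tibble::tibble(copies = 10^(2:6), cq = 35 - 3.3219 * (2:6))
#' fit_standard_curve(d)
fit_standard_curve <- function(dilutions) {
  dilutions <- as_tibble(dilutions)
  stopifnot(all(c("copies", "cq") %in% names(dilutions)))
  if (nrow(dilutions) < 3L) {
    abort("need at least 3 dilution points", class = "dorna_error_input")
  }
  if (any(dilutions$copies <= 0)) {
    abort("copies must be > 0", class = "dorna_error_input")
  }
  span <- diff(range(log10(dilutions$copies)))
  if (span < 2) {
    warn(sprintf("dilution series spans only %.2f log10; slopes may be unstable",
                 span))
  }
  fit <- lm(cq ~ log10(copies), data = dilutions)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    warn("fitted slope is not negative; the curve is not a valid standard curve")
  }
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      r_squared = summary(fit)$r.squared,
      efficiency = 10^(-1 / slope) - 1,
      n = nrow(dilutions),
      fit = fit
    ),
    class = "dorna_stdcurve"
  )
}

#' @export
print.dorna_stdcurve <- function(x, ...) {
  cat(sprintf(
    "<dorna_stdcurve> slope %.4f, intercept %.3f, R^2 %.4f, efficiency %.1f%% (n = %d)\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency, x$n
  ))
  invisible(x)
}

#' Absolute copies from a Cq value
#'
#' Inverts the fitted standard curve: `copies = 10^((cq - intercept) /
#' slope)`; strictly decreasing in Cq for valid (negative-slope) curves.
#'
#' @param cq Numeric Cq value(s).
#' @param curve A [fit_standard_curve()] object.
#' @return Copy numbers, vectorized over `cq`.
#' @export
copies_from_cq <- function(cq, curve) {
  stopifnot(inherits(curve, "dorna_stdcurve"))
  if (curve$slope >= 0) {
    abort("curve slope must be negative", class = "dorna_error_input")
  }
  10^((cq - curve$intercept) / curve$slope)
}

#' Relative quantity from a reference-gene dCq
#'
#' Optional reference-gene (e.g. U6) normalization:
#' `(1 + efficiency)^-(cq_target - cq_reference)`.
#'
#' @param cq_target,cq_reference Cq values for target and reference gene.
#' @param efficiency Amplification efficiency as a fraction (default 1).
#' @return Relative quantities, vectorized.
#' @export
relative_quantity <- function(cq_target, cq_reference, efficiency = 1) {
  (1 + efficiency)^(-(cq_target - cq_reference))
}

#' Per-RNA compartment fractions
#'
#' Normalizes nuclear/cytoplasmic quantities (imaging dot counts or qPCR
#' copies; units are whatever the input is) to fractions summing to 1
#' within each RNA.
#'
#' @param quantities A data frame with columns `rna_id`, `compartment`
#'   and `quantity` (>= 0, not all zero for any RNA).
#' @return The input with an added `fraction` column.
#' @export
#' @examples
#' compartment_fractions(tibble::tibble(
#'   rna_id = "doRNA", compartment = c("nucleus", "cytoplasm"),
#'   quantity = c(25, 75)
#' ))
compartment_fractions <- function(quantities) {
  quantities <- as_tibble(quantities)
  stopifnot(all(c("rna_id", "compartment", "quantity") %in% names(quantities)))
  if (any(quantities$quantity < 0)) {
    abort("quantities must be >= 0", class = "dorna_error_input")
  }
  out <- quantities |>
    dplyr::group_by(.data$rna_id) |>
    dplyr::mutate(fraction = .data$quantity / sum(.data$quantity)) |>
    dplyr::ungroup()
  if (any(!is.finite(out$fraction))) {
    abort("all-zero quantities for at least one RNA", class = "dorna_error_input")
  }
  out
}

#' Dual-luciferase reporter normalization
#'
#' Firefly activity normalized on Renilla activity, expressed as percent
#' of the control condition:
#' `100 * (fluc / rluc) / (control_fluc / control_rluc)`.
#'
#' @param fluc,rluc Sample Firefly and Renilla activities (> 0).
#' @param control_fluc,control_rluc Control-condition activities (> 0).
#' @return Percent of control, vectorized.
#' @export
#' @examples
#' reporter_normalize(50, 100, 100, 100)
reporter_normalize <- function(fluc, rluc, control_fluc, control_rluc) {
  if (any(c(fluc, rluc, control_fluc, control_rluc) <= 0)) {
    abort("all luciferase activities must be > 0", class = "dorna_error_input")
  }
  100 * (fluc / rluc) / (control_fluc / control_rluc)
}

#' Scratch-assay wound closure
#'
#' Percentage of unrecovered scratched area at a time point, and its
#' complement, the percent closure. Areas slightly exceeding the time-zero
#' area (e.g. segmentation jitter) are clamped with a warning.
#'
#' @param area_t0 Scratched area at time zero (> 0).
#' @param area_t Remaining cell-free area at the time point (>= 0).
#' @return A tibble with columns `percent_unrecovered` and
#'   `percent_closure`, vectorized over inputs.
#' @export
#' @examples
#' wound_closure(100, 40)
wound_closure <- function(area_t0, area_t) {
  if (any(area_t0 <= 0)) {
    abort("`area_t0` must be > 0", class = "dorna_error_input")
  }
  if (any(area_t < 0)) {
    abort("`area_t` must be >= 0", class = "dorna_error_input")
  }
  if (any(area_t > area_t0)) {
    warn("`area_t` exceeds `area_t0`; clamping to 100% unrecovered")
    area_t <- pmin(area_t, area_t0)
  }
  unrec <- 100 * area_t / area_t0
  tibble(percent_unrecovered = unrec, percent_closure = 100 - unrec)
}
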