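#' Fit a qPCR standard curve
#'
#' Least-squares regression of Ct on log10 template copies for a serial
#' dilution series, as used for absolute quantification of transcript copy
#' number. The amplification efficiency is derived from the slope as
#' `E = 10^(-1/slope) - 1` (slope -3.3219 corresponds to perfect doubling,
#' E = 100%).
#'
#' @param log10_copies log10 of template copies for each dilution point.
#' @param ct measured Ct values, paired with `log10_copies`.
#' @return object of class `standard_curve` with `points`, `slope`,
#'   `intercept`, `efficiency`, `r_squared`.
#' @examples
#' sc <- fit_standard_curve(log10_copies = 3:7,
#'                          ct = 35 - (3:7 - 3) * 3.3219)
#' sc$efficiency  # 1 (100%)
#' @export
fit_standard_curve <- function(log10_copies, ct) {
  if (length(log10_copies) != length(ct)) stop("paired vectors required")
  if (length(ct) < 3L) stop("at least 3 dilution points required")
  if (diff(range(log10_copies)) < 2) {
    stop("dilution series must span at least 2 log10 units")
  }
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("invalid standard curve: nonnegative slope")
  structure(list(
    points = data.frame(log10_copies = log10_copies, ct = ct),
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    efficiency = 10^(-1 / slope) - 1,
    # noiseless dilution series trigger a spurious perfect-fit warning
    r_squared = suppressWarnings(summary(fit))$r.squared
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: slope %.4f, efficiency %.1f%%, R^2 %.4f\n",
              x$slope, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Absolute quantification from a standard curve
#'
#' Inverts the standard curve, `copies = 10^((ct - intercept)/slope)`, and
#' divides by the number of cells in the assayed sample to give transcript
#' copies per cell. Ct values more than `extrapolation_cycles` outside the
#' calibrated Ct range are refused.
#'
#' @param curve a [fit_standard_curve()] object.
#' @param ct observed Ct value(s).
#' @param n_cells number of cells the template derives from.
#' @param extrapolation_cycles allowed excursion beyond the calibrated Ct
#'   range (cycles).
#' @return numeric vector of copies per cell.
#' @export
quantify_copies <- function(curve, ct, n_cells = 1, extrapolation_cycles = 1) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve")
  if (any(n_cells <= 0)) stop("n_cells must be positive")
  rng <- range(curve$points$ct)
  out_of_range <- ct < rng[1] - extrapolation_cycles |
    ct > rng[2] + extrapolation_cycles
  if (any(out_of_range)) {
    stop(sprintf(
      "Ct value(s) %s outside calibrated range [%.2f, %.2f] +/- %g cycles; refusing to extrapolate",
      paste(format(ct[out_of_range]), collapse = ", "),
      rng[1], rng[2], extrapolation_cycles))
  }
  copies <- 10^((ct - curve$intercept) / curve$slope)
  copies / n_cells
}
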