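# Gyromagnetic ratio of 1H: 42.57747892 MHz/T, equivalently Hz per microtesla.
GAMMA_HZ <- 42.57747892

#' Build a symmetric saturation-offset list
#'
#' Generates the symmetric offset grid from `-half_range_ppm` to
#' `+half_range_ppm` in steps of `step_ppm`. The in-vivo protocol grid
#' (`step 0.2 ppm over +/-6 ppm`) has 61 offsets.
#'
#' @param step_ppm Step size in ppm (> 0).
#' @param half_range_ppm Half range in ppm; must be a non-negative integer
#'   multiple of `step_ppm`.
#' @param descending Logical; order from `+half_range` down to `-half_range`
#'   (the package's storage convention, default) or ascending.
#' @param allow_degenerate Logical; with `half_range_ppm = 0` return the
#'   single offset 0 instead of an error.
#' @return Numeric vector of offsets in ppm, length
#'   `2 * half_range_ppm / step_ppm + 1`.
#' @examples
#' length(make_offset_list(0.2, 6))   # 61
#' length(make_offset_list(0.1, 10))  # 201
#' @export
make_offset_list <- function(step_ppm, half_range_ppm, descending = TRUE,
                             allow_degenerate = FALSE) {
  if (!is.finite(step_ppm) || step_ppm <= 0) stop("step_ppm must be > 0")
  if (!is.finite(half_range_ppm) || half_range_ppm < 0)
    stop("half_range_ppm must be >= 0")
  n_half <- half_range_ppm / step_ppm
  if (abs(n_half - round(n_half)) > 1e-9)
    stop(sprintf(
      "half_range_ppm (%g) is not a multiple of step_ppm (%g)",
      half_range_ppm, step_ppm))
  n_half <- round(n_half)
  if (n_half == 0) {
    if (!allow_degenerate)
      stop(sprintf(
        "degenerate range: half_range_ppm = %g with step_ppm = %g yields a single offset; set allow_degenerate = TRUE for {0}",
        half_range_ppm, step_ppm))
    return(0)
  }
  out <- seq(-n_half, n_half) * step_ppm
  if (descending) rev(out) else out
}
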