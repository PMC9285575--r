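# Voxel-wise Z-spectrum processing: segmentation, smoothing-spline
# interpolation, B0 correction, asymmetry ST computation, quality filtering.

#' Z-spectrum
#'
#' Saturation offsets (ppm, strictly monotone) with normalised water signals.
#' Signals may contain `NA` where a B0-shifted spectrum has no support.
#'
#' @param offsets Offsets in ppm.
#' @param signals Normalised signal intensities (>= 0 or `NA`).
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets, signals) {
  if (length(offsets) != length(signals))
    stop("offsets and signals must have equal length")
  d <- diff(offsets)
  if (length(offsets) > 1 && !(all(d > 0) || all(d < 0)))
    stop("offsets must be strictly monotone")
  s <- signals[!is.na(signals)]
  if (any(!is.finite(s)) || any(s < -1e-12))
    stop("signals must be finite and >= 0")
  structure(list(offsets = as.numeric(offsets),
                 signals = as.numeric(signals)),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets in [%.2f, %.2f] ppm\n",
              length(x$offsets), min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Z-spectrum image stack
#'
#' One 2D slice per saturation offset: `data` is rows x cols x n_offsets,
#' non-negative, with the offset labels carried alongside (no index
#' arithmetic on offsets anywhere downstream).
#'
#' @param data 3D array (rows x cols x offsets), non-negative.
#' @param offsets Offsets in ppm, length matching `dim(data)[3]`.
#' @param frame_time Optional acquisition time in minutes post-injection.
#' @return An object of class `zspectrum_stack`.
#' @export
zspectrum_stack <- function(data, offsets, frame_time = NULL) {
  if (length(dim(data)) != 3L)
    stop("data must be a 3D array (rows x cols x offsets)")
  if (dim(data)[3] != length(offsets))
    stop(sprintf("offset count (%d) does not match data planes (%d)",
                 length(offsets), dim(data)[3]))
  d <- diff(offsets)
  if (length(offsets) > 1 && !(all(d > 0) || all(d < 0)))
    stop("offsets must be strictly monotone")
  if (any(data < -1e-12, na.rm = TRUE)) stop("data must be non-negative")
  structure(list(data = data, offsets = as.numeric(offsets),
                 frame_time = frame_time),
            class = "zspectrum_stack")
}

#' @export
print.zspectrum_stack <- function(x, ...) {
  cat(sprintf("<zspectrum_stack> %d x %d x %d offsets [%.2f, %.2f] ppm%s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$offsets), max(x$offsets),
              if (!is.null(x$frame_time))
                sprintf(", t = %g min", x$frame_time) else ""))
  invisible(x)
}

# Index of the normalisation (S0) frame. Falls back to the most negative
# sampled offset with a warning when s0_offset is not covered.
s0_frame_index <- function(offsets, s0_offset = -10, warn = TRUE) {
  i <- which.min(abs(offsets - s0_offset))
  if (abs(offsets[i] - s0_offset) > 1e-6) {
    i <- which.min(offsets)
    if (warn)
      warning(sprintf(
        "s0 offset %g ppm not sampled; using most negative offset %g ppm",
        s0_offset, offsets[i]))
  }
  i
}

#' Extract the S0 image of a stack
#'
#' @param stack A [zspectrum_stack()].
#' @param s0_offset Normalisation offset in ppm (default -10).
#' @return 2D matrix of S0 intensities.
#' @export
s0_image <- function(stack, s0_offset = -10) {
  stack$data[, , s0_frame_index(stack$offsets, s0_offset)]
}

#' Intensity-threshold foreground segmentation
#'
#' Voxels whose S0 intensity reaches `threshold_fraction` of the
#' 99th-percentile S0 intensity are foreground.
#'
#' @param stack A [zspectrum_stack()].
#' @param threshold_fraction Fraction in (0, 1); default 0.1.
#' @param s0_offset Normalisation offset, ppm.
#' @return Logical matrix; empty (with a warning) when the image is blank.
#' @export
segment_foreground <- function(stack, threshold_fraction = 0.1,
                               s0_offset = -10) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  s0 <- s0_image(stack, s0_offset)
  thr <- threshold_fraction * stats::quantile(s0, 0.99, names = FALSE)
  mask <- s0 >= thr & s0 > 0
  if (!any(mask)) warning("empty foreground mask")
  mask
}

#' Smoothing-spline fit of one voxel's Z-spectrum
#'
#' Fits the sampled spectrum with a cubic smoothing spline, scores the fit
#' with the coefficient of determination R^2 = 1 - SSres/SStot against the
#' raw samples, and locates the bulk-water centre as the argmin of the
#' smooth curve on a dense grid within `search_window` ppm of nominal zero
#' (ties broken toward the smaller |shift|).
#'
#' @param offsets Offsets in ppm (>= 15 values spanning 0).
#' @param signals Normalised signals.
#' @param smoothing `NULL` for generalized cross-validation (default), `0`
#'   for an exact interpolating natural spline, or a positive number used as
#'   the spline's `lambda`.
#' @param search_window Half-width of the water-centre search window, ppm.
#' @param grid_step Dense-grid spacing for the argmin search, ppm.
#' @return An object of class `voxel_fit`: `predict` (function of ppm),
#'   `water_center` (ppm), `r2`, `valid`, `range` (supported ppm range).
#' @export
fit_voxel <- function(offsets, signals, smoothing = NULL,
                      search_window = 1.5, grid_step = 0.001) {
  if (length(offsets) < 15)
    stop("need at least 15 offsets to fit a Z-spectrum")
  if (min(offsets) > -search_window || max(offsets) < search_window)
    stop("offsets must span the water resonance search window")
  invalid <- function(r2 = NA_real_) structure(
    list(predict = NULL, water_center = NA_real_, r2 = r2, valid = FALSE,
         range = range(offsets)), class = "voxel_fit")
  if (any(!is.finite(signals))) return(invalid())
  sstot <- sum((signals - mean(signals))^2)
  if (sstot == 0) return(invalid(r2 = 0))

  pf <- tryCatch({
    if (!is.null(smoothing) && smoothing == 0) {
      stats::splinefun(offsets, signals, method = "natural")
    } else {
      fit <- if (is.null(smoothing))
        stats::smooth.spline(offsets, signals)
      else
        stats::smooth.spline(offsets, signals, lambda = smoothing,
                             all.knots = TRUE)
      function(x) stats::predict(fit, x)$y
    }
  }, error = function(e) NULL)
  if (is.null(pf)) return(invalid())

  ssres <- sum((signals - pf(offsets))^2)
  r2 <- max(0, min(1, 1 - ssres / sstot))

  grid <- seq(max(-search_window, min(offsets)),
              min(search_window, max(offsets)), by = grid_step)
  vals <- pf(grid)
  cand <- which(vals <= min(vals) + 1e-12)
  wc <- grid[cand[which.min(abs(grid[cand]))]]
  structure(list(predict = pf, water_center = wc, r2 = r2, valid = TRUE,
                 range = range(offsets)), class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf("<voxel_fit> centre %+0.3f ppm, R2 = %.4f, %s\n",
              x$water_center, x$r2, if (x$valid) "valid" else "invalid"))
  invisible(x)
}

#' Shift a fitted Z-spectrum so bulk water sits at 0 ppm
#'
#' Resamples the smoothed curve on the common offset grid after moving the
#' estimated water centre to zero frequency. Offsets whose shifted position
#' falls outside the sampled support are set `NA` (never extrapolated).
#'
#' @param fit A valid [fit_voxel()] result.
#' @param offsets Common offset grid to resample on, ppm.
#' @param max_shift Maximum permissible |water_center| in ppm; beyond it the
#'   voxel is invalid and `NULL` is returned.
#' @param shift Shift to apply in ppm; defaults to the fit's own
#'   `water_center`. Supplying an externally estimated shift (e.g. the
#'   baseline frame's map in a dynamic series) decouples B0 referencing from
#'   agent-induced spectral asymmetry.
#' @return A [zspectrum()] with `NA` outside the shifted support, or `NULL`
#'   when the shift exceeds `max_shift`.
#' @export
correct_b0 <- function(fit, offsets, max_shift = 1.5, shift = NULL) {
  stopifnot(inherits(fit, "voxel_fit"))
  if (!fit$valid) stop("cannot B0-correct an invalid voxel fit")
  wc <- if (is.null(shift)) fit$water_center else shift
  if (!is.finite(wc) || abs(wc) > max_shift) return(NULL)
  src <- offsets + wc
  ok <- src >= fit$range[1] & src <= fit$range[2]
  sig <- rep(NA_real_, length(offsets))
  sig[ok] <- pmax(0, fit$predict(src[ok]))
  zspectrum(offsets, sig)
}

#' Asymmetry saturation-transfer fraction
#'
#' `ST = (S(-offset) - S(+offset)) / S0`, evaluated on the (corrected)
#' smoothed spectrum by spline interpolation at exactly +/- the analysis
#' offset.
#'
#' @param spectrum A [zspectrum()] (typically the B0-corrected one).
#' @param analysis_offset Analysis offset in ppm (1.2 in vivo; 0.8 for
#'   in-vitro glucose).
#' @param s0 Normalisation intensity (the smoothed uncorrected signal at
#'   -10 ppm).
#' @return ST as a dimensionless fraction, or `NA` when `s0 <= 0` or either
#'   evaluation point is not covered by the spectrum's support.
#' @examples
#' z <- zspectrum(seq(-2, 2, 0.1), 1 - 0.3 * exp(-seq(-2, 2, 0.1)^2))
#' compute_st(z, 1.2, s0 = 1)  # 0: symmetric spectrum
#' @export
compute_st <- function(spectrum, analysis_offset = 1.2, s0) {
  stopifnot(inherits(spectrum, "zspectrum"))
  if (!is.finite(s0) || s0 <= 0) return(NA_real_)
  ok <- !is.na(spectrum$signals)
  if (sum(ok) < 4) return(NA_real_)
  o <- spectrum$offsets[ok]; s <- spectrum$signals[ok]
  lo <- min(o); hi <- max(o)
  if (-analysis_offset < lo || analysis_offset > hi) return(NA_real_)
  v <- stats::spline(o, s, xout = c(-analysis_offset, analysis_offset),
                     method = "natural")$y
  (v[1] - v[2]) / s0
}

#' R-squared quality filter
#'
#' Voxels pass only with R^2 strictly above the threshold (default 0.97),
#' a valid fit, and foreground membership.
#'
#' @param r2 Matrix of per-voxel R^2.
#' @param r2_threshold Threshold in (0, 1); strict inequality.
#' @param valid Optional logical matrix of fit validity.
#' @param foreground Optional logical foreground matrix.
#' @return Logical matrix.
#' @export
filter_quality <- function(r2, r2_threshold = 0.97, valid = NULL,
                           foreground = NULL) {
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop("r2_threshold must be in (0, 1)")
  mask <- !is.na(r2) & r2 > r2_threshold
  if (!is.null(valid)) mask <- mask & valid
  if (!is.null(foreground)) mask <- mask & foreground
  mask
}

#' Default ST-mapping configuration
#'
#' @param r2_threshold Quality-filter threshold (strict; default 0.97).
#' @param threshold_fraction Foreground segmentation fraction.
#' @param smoothing Spline smoothing (see [fit_voxel()]).
#' @param s0_offset Normalisation offset, ppm.
#' @param max_shift Maximum B0 shift, ppm.
#' @param search_window Water-centre search half-width, ppm.
#' @param shift_map Optional rows x cols matrix of B0 shifts (ppm) to apply
#'   instead of each voxel's own water-centre estimate. Used for dynamic
#'   series, where the field map is estimated once from the pre-injection
#'   frame: B0 does not change after injection, while the growing CEST
#'   shoulder biases per-frame minimum-finding.
#' @return A named list of processing parameters.
#' @export
st_config <- function(r2_threshold = 0.97, threshold_fraction = 0.1,
                      smoothing = NULL, s0_offset = -10, max_shift = 1.5,
                      search_window = 1.5, shift_map = NULL) {
  list(r2_threshold = r2_threshold, threshold_fraction = threshold_fraction,
       smoothing = smoothing, s0_offset = s0_offset, max_shift = max_shift,
       search_window = search_window, shift_map = shift_map)
}

#' Voxel-wise ST parametric map
#'
#' The full per-voxel chain: foreground segmentation, smoothing-spline
#' interpolation, B0 shift correction, asymmetry ST at the analysis offset
#' (S0 taken from the smoothed uncorrected spectrum at `s0_offset`), and
#' R^2 quality filtering. Voxels that fail any stage are masked out, never
#' propagated as numbers.
#'
#' @param stack A [zspectrum_stack()].
#' @param analysis_offset Analysis offset in ppm.
#' @param config Processing parameters from [st_config()].
#' @param verbose Log voxel counts via `message()`.
#' @return An object of class `st_map`: `values` (matrix, `NA` off-mask),
#'   `mask`, `analysis_offset`, `r2`, `water_center`, `frame_time`.
#' @export
st_map <- function(stack, analysis_offset = 1.2, config = st_config(),
                   verbose = FALSE) {
  stopifnot(inherits(stack, "zspectrum_stack"))
  dims <- dim(stack$data)[1:2]
  fg <- withCallingHandlers(
    segment_foreground(stack, config$threshold_fraction, config$s0_offset),
    warning = function(w) {
      if (grepl("empty foreground", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  values <- matrix(NA_real_, dims[1], dims[2])
  r2 <- matrix(NA_real_, dims[1], dims[2])
  wc <- matrix(NA_real_, dims[1], dims[2])
  valid <- matrix(FALSE, dims[1], dims[2])
  i0 <- s0_frame_index(stack$offsets, config$s0_offset, warn = FALSE)
  s0_at <- stack$offsets[i0]
  idx <- which(fg, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    r <- idx[v, 1]; cl <- idx[v, 2]
    sig <- stack$data[r, cl, ]
    fit <- fit_voxel(stack$offsets, sig, smoothing = config$smoothing,
                     search_window = config$search_window)
    r2[r, cl] <- fit$r2
    if (!fit$valid) next
    wc[r, cl] <- fit$water_center
    shift <- if (!is.null(config$shift_map)) config$shift_map[r, cl]
             else fit$water_center
    if (is.na(shift)) next
    corr <- correct_b0(fit, stack$offsets, config$max_shift, shift = shift)
    if (is.null(corr)) next
    s0 <- fit$predict(s0_at)
    st <- compute_st(corr, analysis_offset, s0)
    if (is.na(st)) next
    values[r, cl] <- st
    valid[r, cl] <- TRUE
  }
  mask <- filter_quality(r2, config$r2_threshold, valid, fg)
  values[!mask] <- NA_real_
  if (verbose)
    message(sprintf("st_map: %d foreground, %d valid, %d pass R2 > %.2f",
                    sum(fg), sum(valid), sum(mask), config$r2_threshold))
  structure(list(values = values, mask = mask,
                 analysis_offset = analysis_offset, r2 = r2,
                 water_center = wc, frame_time = stack$frame_time),
            class = "st_map")
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf("<st_map> %d x %d at %+0.1f ppm, %d voxels on mask, mean ST %.4f\n",
              nrow(x$values), ncol(x$values), x$analysis_offset,
              sum(x$mask), mean(x$values[x$mask])))
  invisible(x)
}
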