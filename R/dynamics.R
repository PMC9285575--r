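# Dynamic glucoCEST analysis: Delta-ST% maps, enhanced-pixel fractions, ROI
# time courses, and one-way ANOVA with Dunnett multiple comparisons.

#' Process a dynamic frame series into ST maps
#'
#' Computes [st_map()] for every frame, estimating the B0 shift map from the
#' first (pre-injection) frame only and locking it for all later frames: the
#' static field does not change after injection, whereas the growing agent
#' CEST shoulder biases per-frame water-minimum finding and would otherwise
#' attenuate the apparent signal rise.
#'
#' @param frames List of [zspectrum_stack()] (baseline first).
#' @param analysis_offset ST analysis offset, ppm.
#' @param config Processing parameters from [st_config()].
#' @return List of [st_map()] objects, one per frame.
#' @export
process_series <- function(frames, analysis_offset = 1.2,
                           config = st_config()) {
  if (!length(frames)) stop("need at least one frame")
  base <- st_map(frames[[1]], analysis_offset, config)
  cfg_post <- config
  cfg_post$shift_map <- base$water_center
  c(list(base), lapply(frames[-1], st_map, analysis_offset = analysis_offset,
                       config = cfg_post))
}

#' Post-minus-pre ST change map
#'
#' `Delta-ST% = (ST_post - ST_pre) * 100`, in percentage points, defined on
#' the intersection of the two validity masks.
#'
#' @param pre,post [st_map()] objects with identical geometry and analysis
#'   offset.
#' @return An object of class `delta_st_map`: `values` (percent, `NA`
#'   off-mask), `mask`, `frame_time` (from `post`).
#' @examples
#' # identical maps give an all-zero Delta-ST%
#' @export
delta_st <- function(pre, post) {
  stopifnot(inherits(pre, "st_map"), inherits(post, "st_map"))
  if (!all(dim(pre$values) == dim(post$values)))
    stop("pre and post maps have different geometry")
  if (pre$analysis_offset != post$analysis_offset)
    stop("pre and post maps use different analysis offsets")
  mask <- pre$mask & post$mask
  values <- (post$values - pre$values) * 100
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask,
                 analysis_offset = post$analysis_offset,
                 frame_time = post$frame_time),
            class = "delta_st_map")
}

#' @export
print.delta_st_map <- function(x, ...) {
  cat(sprintf("<delta_st_map> %d x %d, %d voxels, mean %.2f%%%s\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              mean(x$values[x$mask]),
              if (!is.null(x$frame_time))
                sprintf(", t = %g min", x$frame_time) else ""))
  invisible(x)
}

#' Enhanced-pixel fraction
#'
#' Percentage of ROI voxels (on the validity mask) whose Delta-ST% exceeds
#' zero.
#'
#' @param map A [delta_st()] map.
#' @param roi Logical (or 0/1) ROI matrix.
#' @return Percentage in `[0, 100]`, or `NA` (with a warning) when the ROI
#'   and validity mask do not intersect.
#' @export
enhanced_fraction <- function(map, roi) {
  stopifnot(inherits(map, "delta_st_map"))
  roi <- roi > 0
  sel <- roi & map$mask
  if (!any(sel)) {
    warning("ROI does not intersect the validity mask; fraction undefined")
    return(NA_real_)
  }
  100 * mean(map$values[sel] > 0)
}

#' ROI time course of Delta-ST%
#'
#' Per-frame mean, SD and enhanced-pixel fraction of Delta-ST% over the ROI
#' (intersected with each frame's validity mask).
#'
#' @param maps List of [delta_st()] maps (one per post-injection frame).
#' @param roi Logical (or 0/1) ROI matrix.
#' @param subject,group,dose,roi_id Annotation columns for the output rows.
#' @return A data frame with one row per frame: `subject`, `group`, `dose`,
#'   `roi`, `frame_time`, `mean_dst`, `sd_dst`, `enhanced_fraction`,
#'   `n_voxels`.
#' @export
roi_time_course <- function(maps, roi, subject = NA, group = NA,
                            dose = NA, roi_id = 1L) {
  if (!length(maps)) stop("need at least one post-injection frame")
  roi <- roi > 0
  rows <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    sel <- roi & m$mask
    vals <- m$values[sel]
    data.frame(
      subject = subject, group = group, dose = dose, roi = roi_id,
      frame_time = if (!is.null(m$frame_time)) m$frame_time else i,
      mean_dst = if (length(vals)) mean(vals) else NA_real_,
      sd_dst = if (length(vals) > 1) stats::sd(vals) else NA_real_,
      enhanced_fraction = if (length(vals)) 100 * mean(vals > 0) else NA_real_,
      n_voxels = length(vals))
  })
  do.call(rbind, rows)
}

#' One-way ANOVA with Dunnett comparisons against a reference frame
#'
#' Tests for differences in subject-level Delta-ST% across time points:
#' one-way ANOVA F across frames, then Dunnett's two-sided multiple
#' comparisons of every later frame against the reference (by convention the
#' first post-injection frame). Adjusted p-values come from the
#' equicoordinate multivariate-t distribution with the Dunnett product
#' correlation structure (balanced design, rho = 1/2), evaluated by
#' deterministic Gauss-Legendre quadrature.
#'
#' @param values Numeric matrix, subjects x frames (>= 2 subjects, >= 2
#'   frames), of per-subject ROI mean Delta-ST%.
#' @param baseline_frame Column index of the reference frame (default 1).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `dunnett_result`: `F`, `df`, `p_anova`,
#'   `comparisons` (data frame: frame, estimate, t, p_adj, significant),
#'   `degenerate` (TRUE when the residual variance is zero and no inference
#'   is possible).
#' @export
anova_dunnett <- function(values, baseline_frame = 1, alpha = 0.05) {
  values <- as.matrix(values)
  k <- ncol(values); n <- nrow(values)
  if (k < 2) stop("need at least two time points")
  if (n < 2) stop("need at least two subjects per time point")
  if (any(!is.finite(values))) stop("values must be finite")
  if (baseline_frame < 1 || baseline_frame > k) stop("invalid baseline_frame")

  means <- colMeans(values)
  grand <- mean(values)
  ss_between <- n * sum((means - grand)^2)
  ss_within <- sum(sweep(values, 2, means)^2)
  df1 <- k - 1; df2 <- k * (n - 1)
  others <- setdiff(seq_len(k), baseline_frame)

  if (ss_within <= 1e-300 * max(1, abs(grand))) {
    comparisons <- data.frame(frame = others,
                              estimate = means[others] - means[baseline_frame],
                              t = NA_real_, p_adj = NA_real_,
                              significant = FALSE)
    return(structure(list(F = NA_real_, df = c(df1, df2), p_anova = NA_real_,
                          comparisons = comparisons, degenerate = TRUE,
                          alpha = alpha),
                     class = "dunnett_result"))
  }

  mse <- ss_within / df2
  Fstat <- (ss_between / df1) / mse
  p_anova <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)

  m <- length(others)
  tstat <- (means[others] - means[baseline_frame]) / sqrt(2 * mse / n)
  p_adj <- vapply(tstat, function(tt) 1 - dunnett_prob(abs(tt), m, df2),
                  numeric(1))
  p_adj <- pmin(pmax(p_adj, 0), 1)
  comparisons <- data.frame(frame = others,
                            estimate = means[others] - means[baseline_frame],
                            t = tstat, p_adj = p_adj,
                            significant = p_adj < alpha)
  structure(list(F = Fstat, df = c(df1, df2), p_anova = p_anova,
                 comparisons = comparisons, degenerate = FALSE,
                 alpha = alpha),
            class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<dunnett_result> degenerate (zero residual variance); no inference\n")
    return(invisible(x))
  }
  cat(sprintf("<dunnett_result> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p_anova))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
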