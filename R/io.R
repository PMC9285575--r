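# NIfTI stack IO with plain-text offsets sidecar, YAML run configuration.

#' Write a Z-spectrum stack as NIfTI plus offsets sidecar
#'
#' One 3D volume per time frame, stored rows x cols x 1 x offsets (a slice
#' axis of length one is reserved). Offsets go to a plain-text sidecar, one
#' ppm value per line; the frame time, when present, is recorded there as a
#' `# frame_time_min=` comment.
#'
#' @param stack A [zspectrum_stack()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param offsets_path Sidecar path (default: `path` with the NIfTI extension
#'   replaced by `.offsets.txt`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, offsets_path = NULL) {
  stopifnot(inherits(stack, "zspectrum_stack"))
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("path must end in .nii or .nii.gz")
  if (is.null(offsets_path)) offsets_path <- sidecar_path(path)
  d <- stack$data
  dim(d) <- c(dim(d)[1:2], 1L, dim(d)[3])
  RNifti::writeNifti(RNifti::asNifti(d, datatype = "double"), path)
  header <- c(
    "# saturation offsets (ppm), one per line",
    if (!is.null(stack$frame_time))
      sprintf("# frame_time_min=%.10g", stack$frame_time))
  writeLines(c(header, format(stack$offsets, digits = 15, trim = TRUE)),
             offsets_path)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".offsets.txt", path)

#' Read a saturation-offsets sidecar file
#'
#' Blank lines and `#` comment lines are ignored; a `# frame_time_min=`
#' comment, when present, is returned as the `frame_time` attribute.
#'
#' @param path Sidecar path.
#' @return Numeric vector of offsets (ppm), possibly with a `frame_time`
#'   attribute.
#' @export
read_offsets <- function(path) {
  if (!file.exists(path)) stop("offsets sidecar not found: ", path)
  lines <- trimws(readLines(path))
  ft <- grep("^#\\s*frame_time_min=", lines, value = TRUE)
  keep <- lines[nzchar(lines) & !startsWith(lines, "#")]
  offsets <- suppressWarnings(as.numeric(keep))
  if (any(is.na(offsets)))
    stop("non-numeric entries in offsets sidecar: ", path)
  if (length(ft))
    attr(offsets, "frame_time") <-
      as.numeric(sub("^#\\s*frame_time_min=", "", ft[1]))
  offsets
}

#' Read a Z-spectrum stack from NIfTI plus offsets sidecar
#'
#' @param path NIfTI path.
#' @param offsets_path Sidecar path (default derived from `path`).
#' @return A [zspectrum_stack()].
#' @export
read_stack <- function(path, offsets_path = NULL) {
  if (is.null(offsets_path)) offsets_path <- sidecar_path(path)
  img <- RNifti::readNifti(path)
  d <- unclass(img)
  attributes(d) <- list(dim = dim(img))
  if (length(dim(d)) == 4L) {
    if (dim(d)[3] != 1L) stop("expected a single-slice stack")
    dim(d) <- dim(d)[c(1, 2, 4)]
  }
  offsets <- read_offsets(offsets_path)
  if (length(offsets) != dim(d)[3])
    stop(sprintf("offsets sidecar has %d entries but the volume has %d planes",
                 length(offsets), dim(d)[3]))
  zspectrum_stack(d, as.numeric(offsets),
                  frame_time = attr(offsets, "frame_time"))
}

#' Write a 2D parametric map (or mask) as NIfTI
#'
#' @param values Numeric or logical matrix; `NA` is written as `NaN`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, path) {
  m <- values
  if (is.logical(m)) m <- m * 1.0
  dim(m) <- c(dim(values), 1L)
  RNifti::writeNifti(RNifti::asNifti(m, datatype = "double"), path)
  invisible(path)
}

#' Run configuration
#'
#' Round-trippable description of a full simulate-process-analyze run.
#'
#' @param kind `"phantom"` or `"invivo"`.
#' @param agent `"glucose"` or `"3OMG"`.
#' @param B0 Field strength, tesla.
#' @param B1 Saturation amplitude, microtesla.
#' @param duration Saturation duration, s.
#' @param step_ppm,half_range_ppm Offset grid (see [make_offset_list()]).
#' @param s0_offset Normalisation offset, ppm.
#' @param matrix Image matrix size (rows = cols).
#' @param analysis_offset ST analysis offset, ppm.
#' @param r2_threshold Quality-filter threshold.
#' @param threshold_fraction Segmentation threshold fraction.
#' @param snr Simulated signal-to-noise ratio (`Inf` allowed).
#' @param seed Integer seed for every stochastic stage.
#' @param pH_values Vial pH list (phantom runs).
#' @param uptake `"stable"` or `"rising"` (in-vivo runs).
#' @param dose Dose in g/kg (in-vivo runs).
#' @param n_post Number of post-injection frames.
#' @param frame_interval_min Frame spacing, minutes.
#' @param n_subjects Simulated subjects for group statistics (in-vivo runs).
#' @param medium Water preset medium (`"pbs"` for phantoms, `"tissue"`
#'   in vivo; default picked from `kind`).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(kind = c("phantom", "invivo"), agent = "glucose",
                       B0 = 7, B1 = 3, duration = 5,
                       step_ppm = 0.2, half_range_ppm = 6, s0_offset = -10,
                       matrix = 64, analysis_offset = 1.2,
                       r2_threshold = 0.97, threshold_fraction = 0.1,
                       snr = Inf, seed = 1L,
                       pH_values = c(7.4, 7.0, 6.8, 6.6, 6.4, 6.2, 6.0),
                       uptake = "rising", dose = 3, n_post = 5,
                       frame_interval_min = 6, n_subjects = 1L,
                       medium = NULL) {
  kind <- match.arg(kind)
  if (is.null(medium)) medium <- if (kind == "phantom") "pbs" else "tissue"
  cfg <- list(kind = kind, agent = agent, B0 = B0, B1 = B1,
              duration = duration, step_ppm = step_ppm,
              half_range_ppm = half_range_ppm, s0_offset = s0_offset,
              matrix = matrix, analysis_offset = analysis_offset,
              r2_threshold = r2_threshold,
              threshold_fraction = threshold_fraction, snr = snr,
              seed = as.integer(seed), pH_values = pH_values,
              uptake = uptake, dose = dose, n_post = n_post,
              frame_interval_min = frame_interval_min,
              n_subjects = as.integer(n_subjects), medium = medium)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' `Inf` SNR is stored as the string `.inf` per YAML convention and restored
#' on read; the round trip is lossless.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$snr <- as.numeric(raw$snr)  # ".inf" -> Inf
  do.call(run_config, raw)
}

#' @param config A [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# md5 of the canonical YAML serialisation, for run provenance.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}
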