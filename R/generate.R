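# Synthetic phantom and dynamic in-vivo-like stack generators.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. NULL seed = use the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  code
}

# Disk-shaped vial layout: one centre vial plus up to six on a ring.
vial_layout <- function(n, matrix_dim, vial_radius = NULL) {
  rows <- matrix_dim[1]; cols <- matrix_dim[2]
  if (n > 7) stop("default vial geometry holds at most 7 vials")
  r0 <- (rows + 1) / 2; c0 <- (cols + 1) / 2
  vr <- if (is.null(vial_radius)) floor(min(rows, cols) / 9) else vial_radius
  ring <- min(rows, cols) / 2 - vr - 2
  if (ring <= vr) stop("matrix too small for the vial geometry")
  centres <- matrix(c(r0, c0), ncol = 2)
  if (n > 1) {
    ang <- 2 * pi * (seq_len(n - 1) - 1) / 6
    centres <- rbind(centres, cbind(r0 + ring * sin(ang),
                                    c0 + ring * cos(ang)))
  }
  list(centres = centres[seq_len(n), , drop = FALSE], radius = vr)
}

disk_mask <- function(matrix_dim, centre, radius) {
  r <- matrix(seq_len(matrix_dim[1]), matrix_dim[1], matrix_dim[2])
  cl <- matrix(seq_len(matrix_dim[2]), matrix_dim[1], matrix_dim[2],
               byrow = TRUE)
  (r - centre[1])^2 + (cl - centre[2])^2 <= radius^2
}

#' Simulate a multi-vial pH phantom
#'
#' Disk-shaped vials of agent solution on a zero background, one vial per pH
#' value, each voxel drawn from the Bloch-McConnell spectrum at that pH
#' (plus optional noise). Mirrors a titration phantom: 20 mM agent in
#' phosphate buffer at pH 7.4 down to 6.0, imaged at 37 degrees C on a
#' 64 x 64 matrix.
#'
#' @param agent An [agent_model()].
#' @param pH_values pH per vial (default the titration series
#'   7.4, 7.0, 6.8, 6.6, 6.4, 6.2, 6.0).
#' @param concentration_mM Agent concentration (default 20 mM).
#' @param water,sat,acq Water pool, saturation scheme, acquisition config.
#' @param snr Signal-to-noise ratio (`Inf` = noise-free).
#' @param seed RNG seed for the noise.
#' @param vial_radius Vial radius in voxels (default from the matrix size).
#' @return An object of class `phantom_sim`: `stack` ([zspectrum_stack()]),
#'   `labels` (integer matrix, 0 = background), `truth` (per-vial data frame
#'   with ground-truth ST at 0.8 and 1.2 ppm), `spectra` (noise-free
#'   [zspectrum()] per vial).
#' @export
generate_phantom <- function(agent,
                             pH_values = c(7.4, 7.0, 6.8, 6.6, 6.4, 6.2, 6.0),
                             concentration_mM = 20, water, sat, acq,
                             snr = Inf, seed = NULL, vial_radius = NULL) {
  n <- length(pH_values)
  if (n < 1) stop("need at least one vial")
  lay <- vial_layout(n, acq$matrix, vial_radius)
  spectra <- lapply(pH_values, function(p)
    simulate_zspectrum(agent, concentration_mM, p, water, sat, acq))
  offsets <- spectra[[1]]$offsets
  data <- array(0, c(acq$matrix, length(offsets)))
  labels <- matrix(0L, acq$matrix[1], acq$matrix[2])
  for (v in seq_len(n)) {
    m <- disk_mask(acq$matrix, lay$centres[v, ], lay$radius)
    if (any(labels[m] != 0L)) stop("vial layout overlaps; reduce vial_radius")
    labels[m] <- v
    for (i in which(m)) {
      rc <- arrayInd(i, acq$matrix)
      data[rc[1], rc[2], ] <- spectra[[v]]$signals
    }
  }
  stack <- zspectrum_stack(data, offsets)
  if (is.finite(snr)) stack <- add_noise(stack, snr, seed = seed)
  truth <- data.frame(
    vial = seq_len(n), pH = pH_values,
    st_0.8 = vapply(spectra, spectrum_st, numeric(1), analysis_offset = 0.8,
                    s0_offset = acq$s0_offset),
    st_1.2 = vapply(spectra, spectrum_st, numeric(1), analysis_offset = 1.2,
                    s0_offset = acq$s0_offset))
  structure(list(stack = stack, labels = labels, truth = truth,
                 spectra = spectra),
            class = "phantom_sim")
}

#' Agent uptake model for dynamic series
#'
#' Per-post-frame extracellular/intracellular agent concentrations and
#' compartment pH driving the dynamic simulation. `kind = "stable"` models a
#' 3OMG-like plateau (constant concentrations and pH, hence constant
#' ground-truth ST); `kind = "rising"` models glucose-like contrast growth
#' through extracellular acidification (`pH_extra` non-increasing).
#'
#' @param kind `"stable"` or `"rising"`.
#' @param c_extra,c_intra Extracellular/intracellular concentration (mM) per
#'   post-injection frame.
#' @param pH_extra Extracellular pH per post frame.
#' @param pH_intra Fixed intracellular pH (default 7.2).
#' @param dose Injected dose in g/kg (annotation; presets use 1.5 or 3).
#' @param v_extra,v_intra Compartment volume fractions (sum <= 1; the
#'   remainder is agent-free).
#' @return An object of class `uptake_model`.
#' @export
uptake_model <- function(kind = c("stable", "rising"), c_extra, c_intra,
                         pH_extra, pH_intra = 7.2, dose = 3,
                         v_extra = 0.5, v_intra = 0.5) {
  kind <- match.arg(kind)
  n <- length(c_extra)
  if (length(c_intra) != n || length(pH_extra) != n)
    stop("c_extra, c_intra and pH_extra must have one value per post frame")
  if (any(c_extra < 0) || any(c_intra < 0))
    stop("concentrations must be >= 0")
  if (kind == "rising" && any(diff(pH_extra) > 1e-12))
    stop("for kind = 'rising', pH_extra must be non-increasing over time")
  if (v_extra < 0 || v_intra < 0 || v_extra + v_intra > 1)
    stop("volume fractions must be non-negative with sum <= 1")
  structure(list(kind = kind, c_extra = c_extra, c_intra = c_intra,
                 pH_extra = pH_extra, pH_intra = pH_intra, dose = dose,
                 v_extra = v_extra, v_intra = v_intra, n_post = n),
            class = "uptake_model")
}

#' Preset uptake models
#'
#' Dose maps to peak extracellular concentration as 3 g/kg -> 10 mM and
#' 1.5 g/kg -> 5 mM (proportional in between). The stable preset holds both
#' compartments at a plateau; the rising preset holds the extracellular
#' concentration while extracellular pH falls linearly from `pH_start` to
#' `pH_end` over the observation window.
#'
#' @param kind `"stable"` or `"rising"`.
#' @param dose Dose in g/kg (1.5 or 3 for the presets).
#' @param n_post Number of post-injection frames.
#' @param pH_start,pH_end Extracellular pH trajectory for `"rising"`.
#' @return An [uptake_model()].
#' @export
uptake_preset <- function(kind = c("stable", "rising"), dose = 3, n_post = 5,
                          pH_start = 7.0, pH_end = 6.4) {
  kind <- match.arg(kind)
  if (!dose %in% c(1.5, 3))
    warning("presets are calibrated for doses 1.5 and 3 g/kg")
  peak <- 10 * dose / 3
  if (kind == "stable") {
    uptake_model("stable", c_extra = rep(peak, n_post),
                 c_intra = rep(peak / 2, n_post),
                 pH_extra = rep(pH_start, n_post), dose = dose)
  } else {
    uptake_model("rising", c_extra = rep(peak, n_post),
                 c_intra = rep(0, n_post),
                 pH_extra = seq(pH_start, pH_end, length.out = n_post),
                 dose = dose)
  }
}

# Two flank-tumour disks inside a body ellipse.
invivo_geometry <- function(matrix_dim) {
  rows <- matrix_dim[1]; cols <- matrix_dim[2]
  r0 <- (rows + 1) / 2; c0 <- (cols + 1) / 2
  r <- matrix(seq_len(rows), rows, cols)
  cl <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  body <- ((r - r0) / (0.42 * rows))^2 + ((cl - c0) / (0.42 * cols))^2 <= 1
  tr <- max(3, round(min(rows, cols) / 10))
  roi <- matrix(0L, rows, cols)
  roi[disk_mask(matrix_dim, c(r0 - 0.18 * rows, c0 - 0.22 * cols), tr)] <- 1L
  roi[disk_mask(matrix_dim, c(r0 - 0.18 * rows, c0 + 0.22 * cols), tr)] <- 2L
  roi[!body] <- 0L
  list(body = body, roi = roi)
}

#' Simulate a dynamic glucoCEST series
#'
#' Baseline frame (zero agent) plus post-injection frames every
#' `frame_interval_min` minutes. Tumour-ROI voxels mix extracellular and
#' intracellular spectra weighted by the uptake model's volume fractions,
#' each compartment simulated at its own pH; non-tumour body voxels carry the
#' agent-free water spectrum.
#'
#' @param agent An [agent_model()].
#' @param uptake An [uptake_model()].
#' @param water,sat,acq Water pool, saturation scheme, acquisition config.
#' @param n_frames Total frames (baseline + posts); must equal
#'   `uptake$n_post + 1` when supplied.
#' @param frame_interval_min Minutes between frames (default 6).
#' @param snr Signal-to-noise ratio (`Inf` = noise-free).
#' @param seed RNG seed for the noise.
#' @return An object of class `dynamic_sim`: `frames` (list of
#'   [zspectrum_stack()] with `frame_time`), `roi` (integer matrix, two
#'   tumour labels), `truth` (per-frame ground-truth tumour ST at 1.2 ppm),
#'   `spectra` (noise-free tumour spectrum per frame).
#' @export
generate_dynamic_series <- function(agent, uptake, water, sat, acq,
                                    n_frames = NULL, frame_interval_min = 6,
                                    snr = Inf, seed = NULL) {
  stopifnot(inherits(uptake, "uptake_model"))
  if (is.null(n_frames)) n_frames <- uptake$n_post + 1L
  if (n_frames < 2) stop("need at least a baseline and one post frame")
  if (n_frames != uptake$n_post + 1L)
    stop(sprintf("n_frames (%d) does not match uptake model posts + baseline (%d)",
                 n_frames, uptake$n_post + 1L))
  geom <- invivo_geometry(acq$matrix)
  water_z <- simulate_zspectrum(agent, 0, 7.0, water, sat, acq)
  offsets <- water_z$offsets
  v_bg <- 1 - uptake$v_extra - uptake$v_intra

  tumour_spec <- vector("list", n_frames)
  tumour_spec[[1]] <- water_z          # baseline: no agent anywhere
  for (tfr in seq_len(uptake$n_post)) {
    ze <- simulate_zspectrum(agent, uptake$c_extra[tfr], uptake$pH_extra[tfr],
                             water, sat, acq)
    zi <- if (uptake$c_intra[tfr] > 0)
      simulate_zspectrum(agent, uptake$c_intra[tfr], uptake$pH_intra,
                         water, sat, acq) else water_z
    tumour_spec[[tfr + 1]] <- mix_zspectra(
      list(ze, zi, water_z), c(uptake$v_extra, uptake$v_intra, v_bg))
  }

  frames <- vector("list", n_frames)
  times <- (seq_len(n_frames) - 1L) * frame_interval_min
  with_seed(seed, {
    for (fr in seq_len(n_frames)) {
      data <- array(0, c(acq$matrix, length(offsets)))
      for (i in which(geom$body)) {
        rc <- arrayInd(i, acq$matrix)
        src <- if (geom$roi[i] > 0L) tumour_spec[[fr]] else water_z
        data[rc[1], rc[2], ] <- src$signals
      }
      st <- zspectrum_stack(data, offsets, frame_time = times[fr])
      if (is.finite(snr)) st <- add_noise(st, snr)
      frames[[fr]] <- st
    }
  })
  truth <- data.frame(
    frame = seq_len(n_frames), time_min = times,
    st = vapply(tumour_spec, spectrum_st, numeric(1), analysis_offset = 1.2,
                s0_offset = acq$s0_offset))
  structure(list(frames = frames, roi = geom$roi, truth = truth,
                 spectra = tumour_spec),
            class = "dynamic_sim")
}
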