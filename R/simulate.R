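# Bloch-McConnell continuous-wave CEST simulation.
#
# Star topology: each solute pool exchanges with bulk water only. The coupled
# magnetisation evolution under on-resonance-x CW irradiation is linear,
# dM/dt = A M + b, and is propagated in closed form with the matrix
# exponential of the augmented operator [[A, b], [0, 0]].

# Assemble A (3N x 3N) and b for N pools (pool 1 = water) in the frame
# rotating at the saturation frequency. shifts in ppm, offset in ppm,
# B1 in microtesla, B0 in tesla, rates in s^-1.
bm_system <- function(shifts_ppm, R1, R2, f, k, B0, B1_uT, offset_ppm) {
  n <- length(shifts_ppm)
  w1 <- 2 * pi * GAMMA_HZ * B1_uT
  dw <- 2 * pi * GAMMA_HZ * B0 * (shifts_ppm - offset_ppm)  # rad/s
  A <- matrix(0, 3 * n, 3 * n)
  b <- numeric(3 * n)
  kw <- f * k                      # water -> solute back-rates (equilibrium)
  for (j in seq_len(n)) {
    i <- 3L * (j - 1L)
    kj <- if (j == 1L) sum(kw[-1L]) else k[j]
    A[i + 1L, i + 1L] <- -R2[j] - kj
    A[i + 1L, i + 2L] <- dw[j]
    A[i + 2L, i + 1L] <- -dw[j]
    A[i + 2L, i + 2L] <- -R2[j] - kj
    A[i + 2L, i + 3L] <- w1
    A[i + 3L, i + 2L] <- -w1
    A[i + 3L, i + 3L] <- -R1[j] - kj
    b[i + 3L] <- R1[j] * f[j]
    if (j > 1L) {
      for (cc in 0:2) {
        A[i + 1L + cc, 1L + cc] <- A[i + 1L + cc, 1L + cc] + kw[j]
        A[1L + cc, i + 1L + cc] <- A[1L + cc, i + 1L + cc] + k[j]
      }
    }
  }
  list(A = A, b = b)
}

# Longitudinal water magnetisation after tsat seconds of CW saturation at one
# offset, starting from thermal equilibrium.
bm_mz_water <- function(shifts_ppm, R1, R2, f, k, B0, B1_uT, offset_ppm, tsat) {
  sys <- bm_system(shifts_ppm, R1, R2, f, k, B0, B1_uT, offset_ppm)
  n3 <- length(sys$b)
  aug <- rbind(cbind(sys$A, sys$b), 0)
  M0 <- c(as.vector(rbind(0, 0, f)), 1)
  Mt <- as.vector(Matrix::expm(aug * tsat) %*% M0)
  Mt[3L]
}

# Resolve agent pools at a given concentration and pH into the plain numeric
# pool table the solver consumes (water first). Zero-fraction solutes are
# dropped; they cannot influence the water signal.
resolve_pools <- function(agent, concentration_mM, pH, water) {
  ks <- vapply(agent$pools, exchange_rate, numeric(1), pH = pH)
  if (isTRUE(agent$anomer_scaling)) {
    # beta anomer exchanges faster; linear blend around the effective rate
    ks <- ks * (0.7 + 0.6 * agent$anomer_beta_fraction)
  }
  fs <- vapply(agent$pools, function(p)
    p$protons_per_molecule * concentration_mM * 1e-3 /
      water$proton_concentration, numeric(1))
  keep <- fs > 0
  list(
    shifts = c(0, vapply(agent$pools[keep], `[[`, numeric(1),
                         "chemical_shift")),
    R1 = c(1 / water$T1, vapply(agent$pools[keep], function(p) 1 / p$T1,
                                numeric(1))),
    R2 = c(1 / water$T2, vapply(agent$pools[keep], function(p) 1 / p$T2,
                                numeric(1))),
    f = c(1, fs[keep]),
    k = c(0, ks[keep])
  )
}

#' Simulate a Z-spectrum by Bloch-McConnell evolution
#'
#' Propagates the coupled water/solute magnetisation under continuous-wave
#' saturation at every offset of `acq$offsets` (plus the `s0_offset`
#' normalisation frame if it is not already sampled) and returns the water
#' signal normalised by the signal at `s0_offset`.
#'
#' @param agent An [agent_model()].
#' @param concentration_mM Agent concentration in mM (>= 0).
#' @param pH Solution pH in `[5, 9]`.
#' @param water A [water_pool()].
#' @param sat A [saturation_scheme()].
#' @param acq An [acquisition_config()].
#' @return A `zspectrum` object: `offsets` (ppm; `s0_offset` appended when it
#'   was not in `acq$offsets`) and `signals` (normalised so Z = 1 at
#'   `s0_offset`).
#' @examples
#' acq <- acquisition_config(7, make_offset_list(0.5, 4))
#' z <- simulate_zspectrum(agent_preset("glucose"), 20, 6.2,
#'                         water_preset(7, "pbs"), saturation_scheme(3, 5), acq)
#' @export
simulate_zspectrum <- function(agent, concentration_mM, pH, water, sat, acq) {
  stopifnot(inherits(agent, "agent_model"), inherits(water, "water_pool"),
            inherits(sat, "saturation_scheme"),
            inherits(acq, "acquisition_config"))
  if (!is.finite(concentration_mM) || concentration_mM < 0)
    stop("concentration_mM must be finite and >= 0")
  pl <- resolve_pools(agent, concentration_mM, pH, water)
  if (any(pl$f[-1] > 0.1))
    stop("solute pool fraction exceeds 0.1; the dilute-pool model does not apply")
  offsets <- stack_offsets_with_s0(acq$offsets, acq$s0_offset)
  if (sat$B1 == 0) {
    z <- rep(1, length(offsets))
  } else {
    mz <- vapply(offsets, function(o)
      bm_mz_water(pl$shifts, pl$R1, pl$R2, pl$f, pl$k,
                  acq$B0, sat$B1, o, sat$duration), numeric(1))
    s0 <- mz[which.min(abs(offsets - acq$s0_offset))]
    z <- pmax(0, mz / s0)  # on-resonance Mz can undershoot 0 transiently
  }
  zspectrum(offsets, z)
}

# Offsets with the s0 frame appended (if absent) while keeping the list
# strictly monotone. With the descending storage convention a -10 ppm s0
# frame lands at the end.
stack_offsets_with_s0 <- function(offsets, s0_offset) {
  if (any(abs(offsets - s0_offset) < 1e-9)) return(offsets)
  desc <- diff(offsets)[1] < 0
  out <- if (desc) {
    if (s0_offset < min(offsets)) c(offsets, s0_offset)
    else if (s0_offset > max(offsets)) c(s0_offset, offsets)
    else stop("s0_offset falls inside the offset range but is not sampled")
  } else {
    if (s0_offset < min(offsets)) c(s0_offset, offsets)
    else if (s0_offset > max(offsets)) c(offsets, s0_offset)
    else stop("s0_offset falls inside the offset range but is not sampled")
  }
  out
}

# Volume-fraction-weighted mixture of compartment spectra on a shared grid.
mix_zspectra <- function(spectra, weights) {
  stopifnot(length(spectra) == length(weights), sum(weights) > 0)
  sig <- Reduce(`+`, Map(function(z, w) w * z$signals, spectra, weights)) /
    sum(weights)
  zspectrum(spectra[[1]]$offsets, sig)
}

# Exact (spline-interpolated) asymmetry ST of a noise-free spectrum; used
# for simulator ground truth. The measurand is the bulk-water-referenced
# asymmetry, so by default the truth applies the same referencing the
# analysis defines: the asymmetry is taken around the spectral minimum
# (located on a fine grid), not around nominal zero. With a CEST pool
# present the minimum sits slightly downfield of 0 even without any B0
# error, and an ST defined around 0 would not be what the method measures.
spectrum_st <- function(z, analysis_offset, s0_offset = -10,
                        recenter = TRUE) {
  o <- z$offsets; s <- z$signals
  at <- function(x) stats::spline(o, s, xout = x, method = "natural")$y
  wc <- 0
  if (recenter) {
    grid <- seq(max(-1.5, min(o)), min(1.5, max(o)), by = 0.001)
    v <- at(grid)
    cand <- which(v <= min(v) + 1e-12)
    wc <- grid[cand[which.min(abs(grid[cand]))]]
  }
  i0 <- which.min(abs(o - s0_offset))
  (at(wc - analysis_offset) - at(wc + analysis_offset)) / s[i0]
}
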