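# Independent oracle for the Bloch-McConnell solver: the same coupled
# evolution equations transcribed directly and integrated in time with an
# adaptive implicit Runge-Kutta method (deSolve::radau), never touching the
# package's matrix-exponential path.

oracle_gamma <- 42.57747892  # Hz per microtesla

oracle_bm_system <- function(shifts, R1, R2, f, k, B0, B1, off) {
  n <- length(shifts)
  w1 <- 2 * pi * oracle_gamma * B1
  dw <- 2 * pi * oracle_gamma * B0 * (shifts - off)
  A <- matrix(0, 3 * n, 3 * n)
  b <- numeric(3 * n)
  kw <- f * k
  for (j in seq_len(n)) {
    i <- 3 * (j - 1)
    A[i + 1, i + 1] <- -R2[j];           A[i + 1, i + 2] <- dw[j]
    A[i + 2, i + 1] <- -dw[j];           A[i + 2, i + 2] <- -R2[j]
    A[i + 2, i + 3] <- w1;               A[i + 3, i + 2] <- -w1
    A[i + 3, i + 3] <- -R1[j]
    b[i + 3] <- R1[j] * f[j]
    if (j > 1) for (cc in 1:3) {
      A[i + cc, i + cc] <- A[i + cc, i + cc] - k[j]
      A[i + cc, cc] <- A[i + cc, cc] + kw[j]
      A[cc, cc] <- A[cc, cc] - kw[j]
      A[cc, i + cc] <- A[cc, i + cc] + k[j]
    }
  }
  list(A = A, b = b)
}

# Z-spectrum by stiff time integration; normalised at the offset closest to
# s0_offset, matching the solver's convention.
oracle_zspectrum <- function(shifts, R1, R2, f, k, B0, B1, offsets, tsat,
                             s0_offset = -10, rtol = 1e-7, atol = 1e-9) {
  mz <- vapply(offsets, function(off) {
    sys <- oracle_bm_system(shifts, R1, R2, f, k, B0, B1, off)
    M0 <- as.vector(rbind(0, 0, f))
    out <- deSolve::ode(
      M0, c(0, tsat),
      func = function(t, M, p) list(as.vector(sys$A %*% M + sys$b)),
      jacfunc = function(t, M, p) sys$A, jactype = "fullusr",
      method = "radau", rtol = rtol, atol = atol, maxsteps = 500000)
    out[2, 4]
  }, numeric(1))
  pmax(0, mz / mz[which.min(abs(offsets - s0_offset))])
}

# Pool-table view of an agent preset as the oracle needs it.
oracle_pools <- function(agent, concentration_mM, pH, water) {
  ks <- vapply(agent$pools, exchange_rate, numeric(1), pH = pH)
  fs <- vapply(agent$pools, function(p)
    p$protons_per_molecule * concentration_mM * 1e-3 /
      water$proton_concentration, numeric(1))
  list(shifts = c(0, vapply(agent$pools, `[[`, numeric(1), "chemical_shift")),
       R1 = c(1 / water$T1, vapply(agent$pools, function(p) 1 / p$T1,
                                   numeric(1))),
       R2 = c(1 / water$T2, vapply(agent$pools, function(p) 1 / p$T2,
                                   numeric(1))),
       f = c(1, fs), k = c(0, ks))
}
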