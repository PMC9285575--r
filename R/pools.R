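#' Exchangeable proton pool
#'
#' Describes one pool of exchangeable solute protons: its chemical shift
#' relative to bulk water, how many protons per molecule it contributes, its
#' relaxation times, and a base-catalysed pH law for the exchange rate to
#' water (see [exchange_rate()]).
#'
#' @param label Short name, e.g. `"OH"`.
#' @param chemical_shift Shift from the water resonance in ppm
#'   (positive = downfield).
#' @param protons_per_molecule Number of exchangeable protons of this pool
#'   per molecule of agent (>= 1).
#' @param k_ref Exchange rate to water at `pH_ref`, s^-1.
#' @param pH_ref Reference pH at which `k_ref` holds.
#' @param k_0 pH-independent floor rate, s^-1 (buffer-catalysed and
#'   spontaneous exchange). Must satisfy `0 <= k_0 <= k_ref`.
#' @param T1,T2 Longitudinal/transverse relaxation times of the pool, s.
#' @return An object of class `proton_pool`.
#' @seealso [agent_preset()], [exchange_rate()]
#' @export
proton_pool <- function(label, chemical_shift, protons_per_molecule,
                        k_ref, pH_ref = 7.0, k_0 = 0,
                        T1 = 1.0, T2 = 0.01) {
  stopifnot(is.character(label), length(label) == 1L)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(chemical_shift)) stop("chemical_shift must be a finite number (ppm)")
  if (!num1(k_ref) || k_ref <= 0) stop("k_ref must be > 0")
  if (!num1(k_0) || k_0 < 0 || k_0 > k_ref) stop("k_0 must lie in [0, k_ref]")
  if (!num1(protons_per_molecule) || protons_per_molecule < 1)
    stop("protons_per_molecule must be >= 1")
  if (!num1(T1) || !num1(T2) || T2 <= 0 || T1 <= T2)
    stop("relaxation times must satisfy T1 > T2 > 0")
  structure(list(
    label = label,
    chemical_shift = chemical_shift,
    protons_per_molecule = protons_per_molecule,
    k_ref = k_ref, pH_ref = pH_ref, k_0 = k_0,
    k_base = k_ref - k_0,   # so that k(pH_ref) = k_0 + k_base = k_ref
    T1 = T1, T2 = T2
  ), class = "proton_pool")
}

#' @export
print.proton_pool <- function(x, ...) {
  cat(sprintf("<proton_pool> %s @ %+0.2f ppm, %d H, k(%.1f) = %.0f /s, T1 %.2f s, T2 %.3f s\n",
              x$label, x$chemical_shift, x$protons_per_molecule,
              x$pH_ref, x$k_ref, x$T1, x$T2))
  invisible(x)
}

#' CEST agent model
#'
#' A named collection of exchangeable proton pools plus the equilibrium
#' beta-anomer fraction of the sugar. When `anomer_scaling = TRUE`, each
#' pool's effective exchange rate is scaled linearly between a slower alpha
#' and a faster beta rate by the anomer fraction; by default a single
#' effective rate is used.
#'
#' @param name One of `"glucose"`, `"3OMG"`, `"custom"`.
#' @param pools Non-empty list of [proton_pool()] objects.
#' @param anomer_beta_fraction Equilibrium beta-anomer fraction in `[0, 1]`.
#' @param anomer_scaling Logical; apply the anomer rate scaling (default off).
#' @return An object of class `agent_model`.
#' @export
agent_model <- function(name = "custom", pools,
                        anomer_beta_fraction = 0.5,
                        anomer_scaling = FALSE) {
  if (!length(pools)) stop("pools must be non-empty")
  if (!all(vapply(pools, inherits, logical(1), "proton_pool")))
    stop("pools must be a list of proton_pool objects")
  if (anomer_beta_fraction < 0 || anomer_beta_fraction > 1)
    stop("anomer_beta_fraction must be in [0, 1]")
  structure(list(name = name, pools = pools,
                 anomer_beta_fraction = anomer_beta_fraction,
                 anomer_scaling = anomer_scaling),
            class = "agent_model")
}

#' @export
print.agent_model <- function(x, ...) {
  cat(sprintf("<agent_model> %s (%d pool%s, beta fraction %.2f)\n",
              x$name, length(x$pools), if (length(x$pools) > 1) "s" else "",
              x$anomer_beta_fraction))
  for (p in x$pools) print(p)
  invisible(x)
}

#' Built-in agent presets
#'
#' Default hydroxyl-pool models for D-glucose and 3-O-methyl-D-glucose.
#' The paperless quantities of interest here are the rate laws: glucose
#' hydroxyls exchange several-fold faster than 3OMG hydroxyls at any pH, so
#' at a saturation amplitude of a few microtesla glucose is past its optimal
#' exchange regime at neutral pH (contrast grows toward acidic pH) while
#' 3OMG sits near the optimum around pH 7. Rates follow
#' `k(pH) = k_0 + (k_ref - k_0) * 10^(pH - pH_ref)`.
#'
#' `variant = "multi"` for glucose replaces the single effective +1.2 ppm
#' pool by three hydroxyl resonances at +0.8, +1.5 and +2.9 ppm sharing the
#' same rate law.
#'
#' @param name `"glucose"` or `"3OMG"`.
#' @param variant `"single"` (one effective OH pool, default) or `"multi"`
#'   (glucose only).
#' @return An [agent_model()].
#' @export
agent_preset <- function(name = c("glucose", "3OMG"),
                         variant = c("single", "multi")) {
  name <- match.arg(name)
  variant <- match.arg(variant)
  if (name == "glucose") {
    if (variant == "single") {
      pools <- list(proton_pool("OH", 1.2, 5, k_ref = 4000, pH_ref = 7.0,
                                k_0 = 1000))
    } else {
      mk <- function(shift, n) proton_pool(paste0("OH", shift), shift, n,
                                           k_ref = 4000, pH_ref = 7.0,
                                           k_0 = 1000)
      pools <- list(mk(0.8, 2), mk(1.5, 2), mk(2.9, 1))
    }
    agent_model("glucose", pools, anomer_beta_fraction = 0.64)
  } else {
    if (variant == "multi")
      stop("multi-pool variant is defined for glucose only")
    pools <- list(proton_pool("OH", 1.2, 4, k_ref = 800, pH_ref = 7.0,
                              k_0 = 150))
    agent_model("3OMG", pools, anomer_beta_fraction = 0.58)
  }
}

#' pH-dependent exchange rate of a proton pool
#'
#' Base-catalysed exchange law
#' `k(pH) = k_0 + k_base * 10^(pH - pH_ref)` with
#' `k_base = k_ref - k_0`, so that `k(pH_ref) = k_ref` and the rate grows
#' tenfold per pH unit above the floor. Monotone non-decreasing in pH.
#'
#' @param pool A [proton_pool()].
#' @param pH Numeric pH value(s) in `[5, 9]`.
#' @return Exchange rate(s) in s^-1.
#' @examples
#' p <- agent_preset("glucose")$pools[[1]]
#' exchange_rate(p, 7.0)  # == p$k_ref
#' @export
exchange_rate <- function(pool, pH) {
  stopifnot(inherits(pool, "proton_pool"))
  if (any(!is.finite(pH)) || any(pH < 5) || any(pH > 9))
    stop("pH must lie in [5, 9]")
  pool$k_0 + pool$k_base * 10^(pH - pool$pH_ref)
}

#' Bulk water pool
#'
#' @param T1,T2 Water relaxation times, s (`T1 > T2 > 0`).
#' @param proton_concentration Water proton concentration in M
#'   (default 2 x 55.5).
#' @return An object of class `water_pool`.
#' @export
water_pool <- function(T1, T2, proton_concentration = 111) {
  if (!is.finite(T1) || !is.finite(T2) || T2 <= 0 || T1 <= T2)
    stop("water relaxation times must satisfy T1 > T2 > 0")
  if (proton_concentration <= 0) stop("proton_concentration must be > 0")
  structure(list(T1 = T1, T2 = T2,
                 proton_concentration = proton_concentration),
            class = "water_pool")
}

#' Water relaxation presets per field strength
#'
#' Literature-typical water T1/T2 at 3 T and 7 T for tumour-like tissue and
#' for buffered aqueous solutions (phantoms) at 37 degrees C.
#'
#' @param B0 Field strength in tesla; 3 and 7 have presets.
#' @param medium `"tissue"` or `"pbs"`.
#' @return A [water_pool()].
#' @export
water_preset <- function(B0, medium = c("tissue", "pbs")) {
  medium <- match.arg(medium)
  tab <- list(
    tissue = list(`3` = c(1.5, 0.080), `7` = c(2.0, 0.050)),
    pbs    = list(`3` = c(2.8, 0.800), `7` = c(3.3, 0.600))
  )
  key <- as.character(B0)
  if (is.null(tab[[medium]][[key]]))
    stop("no water preset for B0 = ", B0, " T; supply water_pool() directly")
  v <- tab[[medium]][[key]]
  water_pool(T1 = v[1], T2 = v[2])
}

#' Continuous-wave saturation scheme
#'
#' @param B1 Saturation amplitude in microtesla (>= 0).
#' @param duration Saturation duration in seconds (> 0).
#' @param shape Pulse shape; only `"block"` (continuous wave) is supported.
#' @return An object of class `saturation_scheme`.
#' @export
saturation_scheme <- function(B1 = 2, duration = 5, shape = "block") {
  if (!is.finite(B1) || B1 < 0) stop("B1 must be >= 0")
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  shape <- match.arg(shape, "block")
  structure(list(B1 = B1, duration = duration, shape = shape),
            class = "saturation_scheme")
}

#' Acquisition configuration
#'
#' @param B0 Main field strength, tesla.
#' @param offsets Saturation offsets in ppm, strictly monotone. If
#'   `s0_offset` is not among them it is acquired as an extra frame.
#' @param s0_offset Offset of the normalisation frame, ppm (default -10).
#' @param matrix Image matrix `(rows, cols)`.
#' @param temperature Sample temperature, degrees C (annotation only).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(B0, offsets, s0_offset = -10,
                               matrix = c(64, 64), temperature = 37) {
  if (!is.finite(B0) || B0 <= 0) stop("B0 must be > 0")
  d <- diff(offsets)
  if (length(offsets) < 2 || !(all(d > 0) || all(d < 0)))
    stop("offsets must be strictly monotone")
  if (length(matrix) != 2 || any(matrix < 1))
    stop("matrix must be (rows, cols)")
  structure(list(B0 = B0, offsets = as.numeric(offsets),
                 s0_offset = s0_offset,
                 matrix = as.integer(matrix), temperature = temperature),
            class = "acquisition_config")
}
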