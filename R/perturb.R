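# Controlled corruptions of simulated stacks: B0 field inhomogeneity and
# measurement noise, each returning its ground truth for testing recovery.

#' Field-map specification
#'
#' @param type `"constant"` (uniform shift), `"polynomial"` (smooth low-order
#'   surface, coefficients drawn once under `seed` in [add_b0_field()]), or
#'   `"uniform"` (i.i.d. per-voxel shifts, for recovery benchmarks).
#' @param shift_ppm Shift for `"constant"`, ppm.
#' @param max_ppm Peak |shift| for `"polynomial"`/`"uniform"`, ppm.
#' @param degree Polynomial surface degree.
#' @return A named list consumed by [add_b0_field()].
#' @export
fieldmap_spec <- function(type = c("constant", "polynomial", "uniform"),
                          shift_ppm = 0, max_ppm = 0.3, degree = 2) {
  type <- match.arg(type)
  list(type = type, shift_ppm = shift_ppm, max_ppm = max_ppm, degree = degree)
}

# Materialise a fieldmap spec (or pass a ppm matrix through).
build_fieldmap <- function(spec, matrix_dim, seed = NULL) {
  if (is.matrix(spec)) {
    if (!all(dim(spec) == matrix_dim)) stop("fieldmap matrix dimension mismatch")
    return(spec)
  }
  rows <- matrix_dim[1]; cols <- matrix_dim[2]
  switch(spec$type,
    constant = matrix(spec$shift_ppm, rows, cols),
    polynomial = with_seed(seed, {
      x <- matrix(seq(-1, 1, length.out = rows), rows, cols)
      y <- matrix(seq(-1, 1, length.out = cols), rows, cols, byrow = TRUE)
      s <- matrix(0, rows, cols)
      for (i in 0:spec$degree) for (j in 0:(spec$degree - i))
        s <- s + stats::runif(1, -1, 1) * x^i * y^j
      if (max(abs(s)) > 0) s <- s * spec$max_ppm / max(abs(s))
      s
    }),
    uniform = with_seed(seed,
      matrix(stats::runif(rows * cols, -spec$max_ppm, spec$max_ppm),
             rows, cols))
  )
}

#' Impose a B0 inhomogeneity field on a stack
#'
#' Resamples every voxel's spectrum as if its water centre sat at the
#' per-voxel field-map shift: the value at offset `o` becomes the original
#' spectrum's value at `o - shift`. Returns the ground-truth shift map for
#' recovery benchmarking. A zero field map returns the stack unchanged.
#'
#' @param stack A [zspectrum_stack()].
#' @param fieldmap A [fieldmap_spec()] or a rows x cols matrix of shifts
#'   (ppm).
#' @param seed RNG seed for random field maps.
#' @return List with `stack` (shifted [zspectrum_stack()]) and `shift`
#'   (ground-truth ppm matrix).
#' @export
add_b0_field <- function(stack, fieldmap, seed = NULL) {
  stopifnot(inherits(stack, "zspectrum_stack"))
  dims <- dim(stack$data)[1:2]
  shift <- build_fieldmap(fieldmap, dims, seed)
  half_range <- (max(stack$offsets) - min(stack$offsets)) / 2
  if (max(abs(shift)) > half_range)
    stop("field-map shift exceeds half the sampled offset range")
  if (all(shift == 0)) return(list(stack = stack, shift = shift))
  lo <- min(stack$offsets); hi <- max(stack$offsets)
  data <- stack$data
  for (i in which(matrix(TRUE, dims[1], dims[2]))) {
    rc <- arrayInd(i, dims)
    sig <- stack$data[rc[1], rc[2], ]
    if (all(sig == 0) || shift[i] == 0) next
    src <- pmin(hi, pmax(lo, stack$offsets - shift[i]))
    data[rc[1], rc[2], ] <- pmax(0, stats::spline(
      stack$offsets, sig, xout = src, method = "natural")$y)
  }
  list(stack = zspectrum_stack(data, stack$offsets, stack$frame_time),
       shift = shift)
}

#' Add measurement noise to a stack
#'
#' Noise standard deviation is `reference / snr`, where the reference is the
#' median positive intensity of the S0 (unsaturated) frame. Gaussian noise is
#' clamped at zero (magnitude data); Rician noise is the magnitude of the
#' complex signal with i.i.d. Gaussian components.
#'
#' @param stack A [zspectrum_stack()].
#' @param snr Signal-to-noise ratio (> 0; `Inf` returns the stack unchanged).
#' @param model `"gaussian"` (default) or `"rician"`.
#' @param seed RNG seed.
#' @return A [zspectrum_stack()].
#' @export
add_noise <- function(stack, snr, model = c("gaussian", "rician"),
                      seed = NULL) {
  stopifnot(inherits(stack, "zspectrum_stack"))
  model <- match.arg(model)
  if (!is.numeric(snr) || length(snr) != 1 || snr <= 0)
    stop("snr must be a positive number")
  if (is.infinite(snr)) return(stack)
  s0 <- s0_image(stack)
  ref <- stats::median(s0[s0 > 0])
  if (!is.finite(ref)) ref <- 1
  sd <- ref / snr
  data <- with_seed(seed, {
    n <- length(stack$data)
    if (model == "gaussian") {
      x <- stack$data + array(stats::rnorm(n, 0, sd), dim(stack$data))
      x[x < 0] <- 0  # magnitude data
      x
    } else {
      sqrt((stack$data + array(stats::rnorm(n, 0, sd), dim(stack$data)))^2 +
             array(stats::rnorm(n, 0, sd), dim(stack$data))^2)
    }
  })
  zspectrum_stack(data, stack$offsets, stack$frame_time)
}
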