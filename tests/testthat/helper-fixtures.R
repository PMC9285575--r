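# Shared small fixtures, built in code at test time.

# Coarse in-vitro-like acquisition: +/-6 ppm at 0.25 ppm (49 offsets + S0).
small_acq <- function(B0 = 7, matrix = c(32, 32), step = 0.25, half = 6)
  acquisition_config(B0, make_offset_list(step, half), matrix = matrix)

sat3 <- function() saturation_scheme(3, 5)
sat2 <- function() saturation_scheme(2, 5)

# ST read directly off a simulated (noise-free) zspectrum, via the exported
# asymmetry evaluator, normalising at the spectrum's own S0 frame.
st_of <- function(z, analysis_offset = 1.2, s0_offset = -10)
  compute_st(z, analysis_offset,
             s0 = z$signals[which.min(abs(z$offsets - s0_offset))])

# Smooth synthetic Z-spectrum shape (direct water saturation + one CEST dip)
# for tests that do not need the physics engine.
zshape <- function(offsets, center = 0, depth = 0.85, cest = 0.08)
  1 - depth * exp(-((offsets - center) / 0.6)^2) -
    cest * exp(-((offsets - center - 1.2) / 0.8)^2)
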