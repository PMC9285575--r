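# glucocest

Simulation and analysis of dynamic glucose-enhanced CEST MRI in R.

Chemical exchange saturation transfer (CEST) imaging turns D-glucose and its
non-metabolisable analog 3-O-methyl-D-glucose (3OMG) into injectable MRI
contrast agents: a long off-resonance pulse saturates their exchangeable
hydroxyl protons (0.8-3 ppm downfield of water), and exchange carries the
saturation into bulk water, attenuating the signal. The contrast metric is
the Z-spectrum asymmetry

    ST = ( S(-d) - S(+d) ) / S0 ,        d = 1.2 ppm,  S0 = S(-10 ppm)

and, for dynamic studies, the post-minus-pre-injection change
`ΔST% = (ST_post − ST_pre) × 100` plus the *enhanced-pixel fraction* (the
percentage of tumour-ROI voxels with ΔST% > 0). The package is aimed at
CEST methods developers and preclinical imaging groups who need a tested,
ground-truth-validated implementation of this processing chain — and a
physics simulator to validate it against.

Two halves, sharing one set of data structures:

* **Simulator** — multi-pool Bloch–McConnell continuous-wave evolution
  solved in closed form (matrix exponential), with base-catalysed
  pH-dependent exchange (`k(pH) = k₀ + (k_ref − k₀)·10^(pH − pH_ref)`),
  agent presets for glucose and 3OMG, titration phantoms (pH 7.4 → 6.0,
  20 mM in buffer), dynamic tumour-uptake series with stable (3OMG-like)
  and rising (glucose-like, extracellular acidification) kinetics, B0
  field-map corruption and Gaussian/Rician noise — every corruption
  returning its ground truth.
* **Analysis** — per-voxel chain: intensity-threshold segmentation,
  smoothing-spline (GCV) Z-spectrum interpolation, B0 recentring via the
  spline minimum, asymmetry ST with an R² > 0.97 quality filter; ΔST% maps,
  ROI time courses, enhanced fractions; one-way ANOVA with Dunnett multiple
  comparisons of later frames against the first post-injection frame.

## Worked example

Simulate the seven-vial pH phantom at 7 T (3 µT × 5 s saturation, in-vitro
0.1-ppm sampling), process it to an ST map, and compare against ground
truth:

```r
library(glucocest)

acq <- acquisition_config(7, make_offset_list(0.1, 10), matrix = c(64, 64))
ph  <- generate_phantom(agent_preset("glucose"),
                        water = water_preset(7, "pbs"),
                        sat = saturation_scheme(3, 5), acq = acq,
                        snr = 100, seed = 1)
sm  <- st_map(ph$stack, analysis_offset = 1.2)
vial_table(sm, ph)
```

```
  vial  pH n_voxels    mean_st      sd_st    truth_st
1    1 7.4      156 0.01188205 0.00982802 0.003866051
2    2 7.0      156 0.05996082 0.01115908 0.062316975
3    3 6.8      154 0.09188588 0.01133032 0.101949759
4    4 6.6      154 0.12621530 0.01379778 0.138820750
5    5 6.4      156 0.15105699 0.01184616 0.167365967
6    6 6.2      154 0.17096651 0.01329801 0.188156049
7    7 6.0      154 0.18289596 0.01291688 0.200921050
```

The measured per-vial mean ST tracks the simulator's ground truth and shows
the glucose signature: contrast rising monotonically toward acidic pH
(≈ 18 % at pH 6.0 versus ≈ 1 % at 7.4 under these conditions), the opposite
of the 3OMG preset, which peaks near neutral pH. A dynamic in-vivo-like run
is one call — `run_pipeline(run_config("invivo", uptake = "rising"),
"out/")` — and writes ΔST% maps, ROI time-course CSVs, Dunnett statistics
and a parametric overlay PNG into a deterministic, config-hashed directory.

A command-line wrapper over the same functions ships at
`inst/cli/glucocest.R` (`simulate`, `process`, `analyze`, `run`
subcommands). Details of the model, parameter choices and numerical
behaviour are in `vignettes/glucocest-methods.Rmd`.

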