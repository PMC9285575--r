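Package: glucocest
Title: Simulation and Analysis of Dynamic Glucose-Enhanced CEST MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for chemical exchange saturation transfer (CEST) MRI of
    exchangeable hydroxyl protons, centred on glucoCEST imaging of D-glucose
    and 3-O-methyl-D-glucose. Provides a multi-pool Bloch-McConnell
    continuous-wave simulator with pH-dependent exchange rates, synthetic
    phantom and dynamic in-vivo-like Z-spectrum stacks, voxel-wise
    smoothing-spline interpolation with B0 inhomogeneity correction,
    asymmetry saturation-transfer (ST) mapping with R-squared quality
    filtering, post-injection Delta-ST dynamics with enhanced-pixel
    statistics, and one-way ANOVA with Dunnett multiple comparisons across
    time points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    multcomp,
    mvtnorm,
    optparse,
    withr
Config/testthat/edition: 3
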