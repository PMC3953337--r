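Package: cndnma
Title: All-Atom Normal Mode Analysis with Contact-Number Diffusion and
    Elastic Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: All-atom normal mode analysis (NMA) of protein structures under
    two native-centric models: the classical elastic network model (ENM), in
    which every contacting atom pair is restrained by a Hookean spring, and
    the contact-number diffusion model (CND), which replaces the O(N^2)
    pairwise restraints by O(N) restraints -- specific distance restraints on
    sequence-local atom pairs plus semi-specific per-atom restraints on
    non-local contact numbers, imposed through Lagrange multipliers so that
    the native structure is a stationary point. Provides PDB input/output
    and synthetic fixtures, analytic Hessians with finite-difference oracles,
    mass-weighted eigendecomposition, mean-square fluctuations, cumulative
    least-squares fitting of normal modes to apo-holo conformational changes,
    trajectory principal component analysis, Shrake-Rupley accessible surface
    area, and B-factor correlation with bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
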