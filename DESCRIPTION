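Package: microrheo
Title: Passive Particle-Tracking Microrheology from Bead Videos and Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Broadband passive microrheology from the thermal motion of
    micron-scale probe particles. Simulates Brownian dynamics of free,
    optically trapped, gel-embedded and near-wall beads with known ground
    truth; extracts 2D and 3D trajectories from transmission videos,
    including nine-plane multiplane frames with sharpness-based axial
    localization; detrends and notch-filters trajectories; computes mean
    squared displacement, directional MSD and the normalized position
    autocorrelation function; converts motion statistics to creep
    compliance, complex shear moduli via the generalized Stokes-Einstein
    relation, plateau modulus, trap stiffness, NPAF relative viscosity and
    angle-resolved viscosity with near-wall drag predictions; and relates
    per-probe rheology to triangular surface meshes of cell clusters
    through exact point-to-mesh distances.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
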