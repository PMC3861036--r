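Package: ureatraj
Title: Trajectory Metrics for Early-Stage Chemical Unfolding of Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis battery for molecular-dynamics trajectories of proteins
    solvated in water/urea boxes, aimed at the early (quasi-native) stages of
    chemical denaturation. Provides per-frame structure descriptors (RMSD,
    radius of gyration, Shrake-Rupley SASA with polar/apolar partition,
    TM-score, simplified DSSP secondary structure, native-structure indexes),
    native-contact kinetics (contact timelines, opening-time statistics,
    per-residue lost-contact time), first-solvation-shell composition and
    urea-preference coefficients, solvent residence events, geometric
    hydrogen-bond detection with occupancy filtering, flexibility and
    transport metrics (RMSF, time-lag RMSD, mean-square displacement and
    Einstein diffusion), and a synthetic-trajectory generator with exact
    ground truth so the whole pipeline can be exercised without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
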