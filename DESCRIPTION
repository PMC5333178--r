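Package: ligandpath
Title: Attribute Derivation and Multi-Scale Simplification of Ligand
    Transport Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring how a small ligand travels through a
    protein in a molecular-dynamics simulation. Reads multi-model PDB
    trajectories (with optional PQR partial charges, CAVER-style tunnel
    sphere profiles and an active-site residue list), derives per-time-step
    geometric and physico-chemical attributes of the ligand path
    (stuckness, distance and direction to the active site, free-space
    radius from an imported or temporal tunnel, lining residues,
    hydrophobicity and charge profiles, speed, residue turnover), assigns
    each step a four-way positional category (outside, surface, inside,
    active site), and simplifies the noisy trajectory at multiple scales
    using a local complexity measure with Savitzky-Golay (smoothing) and
    Douglas-Peucker (vertex-preserving) back ends, both interactively per
    interval and automatically. A deterministic synthetic scenario
    generator produces fully labelled protein + ligand fixtures for
    validation, and reporting helpers export the trajectory overview,
    lining-residue timelines and scatter data as tables and static plots.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
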