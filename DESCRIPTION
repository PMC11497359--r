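Package: trajmetrics
Title: Domain-Resolved Trajectory Stability, Ligand Contact Occupancy,
    and Cell Migration Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis of molecular-dynamics trajectories and single-cell
    migration tracks. Parses protein structures from PDB text, defines named
    structural domains as chain-scoped residue ranges, and computes per-domain
    root-mean-square deviation (Kabsch superposition) and per-residue
    root-mean-square fluctuation with domain-wise box statistics. Implements a
    transient ligand contact-number statistic: the number of ligand copies
    whose centre of mass lies within a distance cutoff of a residue's centre
    of mass, evaluated on a fixed time grid, averaged, summed into domain
    contact numbers, and tabulated into mixture competition matrices; contact
    hotspots can be written back into the B-factor column of a PDB file for
    visualisation. Also provides single-cell track kinematics (velocity,
    accumulated and Euclidean distance, directional persistence) with
    Mann-Whitney two-group comparison, synthetic generators (lattice proteins,
    diffusing ligands, harmonic fluctuations, rigid motions, persistent random
    walks) with analytically known ground truth, and a reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
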