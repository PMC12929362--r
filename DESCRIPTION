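Package: aptaconv
Title: In Silico Conversion of ssRNA Aptamer Models to ssDNA with
    Conformational Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts three-dimensional single-stranded RNA aptamer models
    into chemically consistent single-stranded DNA models while preserving
    the parent conformation exactly: removal of the ribose 2'-hydroxyl,
    geometric construction of the thymine C5 methyl group in the base
    plane, and residue renaming to standard DNA codes, with a per-structure
    audit report and chemical validation against idealized residue
    templates.  Ships from-scratch molecular-dynamics descriptors used to
    judge conformational preservation: weighted Kabsch superposition RMSD
    time series, geometric intramolecular hydrogen-bond counting with
    GROMACS-convention criteria, plateau-onset detection, and grid
    summaries of per-run means and standard deviations.  Includes readers
    and writers for PDB (v2/v3 naming dialects) and GRO coordinate files,
    multi-model PDB trajectories, an idealized single-stranded helix and
    synthetic-trajectory fixture generator with known ground truth,
    emission of GROMACS-style molecular-dynamics parameter files and run
    plans, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
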