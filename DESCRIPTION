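Package: mechgate
Title: Geometry, Pore Profiling and Tension-Gating Energetics of
    Mechanosensitive Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of mechanosensitive channel gating by the
    "flattening and expansion" mechanism. Reads closed/open channel structures
    (PDB/mmCIF), detects rotational symmetry and places models in a canonical
    pore-axis frame; measures midplane bending angle, in-plane cross-sectional
    area, transmembrane-domain height and periplasmic ring diameter; profiles
    the ion-conduction pore with a deterministic sphere probe and locates
    hydrophobic gates with residue attribution; evaluates the membrane-tension
    gating free-energy model (bending energy, midpoint tension in closed form
    and by root finding, open-probability curves); and analyses single-channel
    pressure-ramp recordings (unitary conductance, first-activation pressure,
    tension-sensitivity ratio against an in-patch calibrator channel).
    Ground-truthed synthetic structures and recordings are generated for
    end-to-end validation.
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
    grDevices,
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
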