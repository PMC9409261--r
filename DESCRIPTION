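Package: helixhb
Title: Hydrogen-Bond Energetics of 3_10- and Alpha-Helical Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds capped oligoalanine helix models at prescribed backbone
    dihedral angles, enumerates their backbone hydrogen bonds, and analyses
    their energetics with a fragment-based energy decomposition (the
    negative fragmentation approach), a point-charge/Lennard-Jones molecular
    mechanics hydrogen-bond energy, electron-density difference algebra on
    Gaussian-cube volumetric grids, and Hirshfeld-charge local dipole
    moments of the carbonyl and amide groups. The quantum-chemistry engine
    is abstracted behind an energy backend so the whole pipeline runs and is
    validated with synthetic fixtures and externally supplied energy,
    density, and charge tables.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
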