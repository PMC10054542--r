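Package: implimem
Title: Implicit Lipid Bilayer Models for Protein Insertion Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Energy models for protein insertion into implicit lipid
    bilayers of planar, double, and arbitrary mesh-defined shape. The
    bilayer is a continuum field interpolating between water and the
    hydrocarbon core across the headgroup region; insertion energies are
    per-area transfer energies weighted by solvent-accessible surface and
    the local membrane profile. Includes structural parameter sets for
    common phospholipids, per-residue calibration of atom and bead
    transfer energies against any reference hydrophobicity scale,
    all-atom, coarse-grained and one-bead-per-residue representations,
    signed-depth computation against triangulated membrane meshes,
    rigid-body Metropolis Monte Carlo and gradient relaxation, elastic
    network flexibility, and insertion analytics (depth, tilt, roll,
    per-residue depth profiles, energy scans).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
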