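Package: ballmill
Title: Wall-Force Model of Mechanochemical Activation Under Ball Milling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the mechanically induced change in a reaction's
    activation energy under ball-milling conditions from the reactant
    (or pre-reactive adduct) and transition-state geometries and an
    impact pressure. A ball impact is idealised as two rigid walls
    compressing the molecule along a direction; the compressive force,
    set by the impact pressure acting on the molecular cross-section,
    performs work along the straight-line reaction displacement obtained
    from a mass-weighted Kabsch superposition of the two geometries.
    Sweeping all impact orientations on a uniform spherical grid yields a
    directional map of the barrier change and its spherical average.
    Includes an XYZ reader/writer with an embedded element table,
    synthetic fixture generators with analytically known mechanical work,
    pressure scans, pathway comparison reports, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
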