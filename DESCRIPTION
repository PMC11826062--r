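Package: serpenergy
Title: Bioenergetics of Methanogenesis in Serpentinized Fluids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the energetic habitability of serpentinized
    (hyperalkaline, H2-rich) fluids for hydrogenotrophic, formatotrophic and
    acetoclastic methanogenesis. Distributes measured totals of dissolved
    inorganic carbon, formate and acetate into aqueous species with Davies
    activity corrections, computes chemical affinities (kJ per mole CH4) and
    limiting-reactant energy supplies (J per kg fluid) for the three
    methanogenic metabolisms, bounds the diffusive flux of each substrate to a
    cell-sized sphere, models conservative two-end-member fluid mixing with Si
    as the tracer, and generates seeded synthetic fluid chemistries for
    testing. Ships a compiled field dataset of surface-expressed and well
    fluids from the Samail Ophiolite (Oman).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
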