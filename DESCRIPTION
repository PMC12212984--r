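Package: pamdiv
Title: Cetacean Community Assemblage Analysis from Passive Acoustic Detections
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Biodiversity and community-assemblage analysis of daily
    passive-acoustic detection records of cetaceans. Bins validated daily
    species detections into monthly relative acoustic presence, computes
    effective-number-of-species (inverse Simpson) and species exchange
    ratios (richness-based SERr, congruent with Jaccard dissimilarity, and
    abundance-based SERa, congruent with Wishart dissimilarity) between
    consecutive months, partitions monitoring sites by per-species monthly
    detection days with conditional inference trees (permutation-test
    recursive partitioning with Strasser-Weber moments), and draws acoustic
    niche (spectrographic box) displays of daily presence in species-typical
    calling-frequency bands. A seeded synthetic community generator emulates
    shelf-break monitoring arrays with resident, seasonal-migrant and
    latitudinally bounded species so the whole pipeline is testable without
    field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan
Config/testthat/edition: 3
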