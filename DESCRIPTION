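Package: serpenergy
Title: Catabolic Bioenergetics of Methane Cycling in Serpentinizing Spring Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the chemical energy available to
    methane-cycling microorganisms in hyperalkaline serpentinizing spring
    fluids. From measured fluid geochemistry (pH, temperature, dissolved
    inorganic and organic carbon, methane, hydrogen, nitrogen and phosphorus
    species) the package performs equilibrium aqueous speciation at fixed pH,
    evaluates in-situ Gibbs energies (dG = dG0 + RT ln Q) for
    hydrogenotrophic and acetoclastic methanogenesis, anaerobic methane
    oxidation coupled to sulfate or nitrate reduction, and aerobic methane
    oxidation, and converts them into free-energy yields per liter of fluid
    under configurable scenario assumptions for unmeasured substrates.
    A companion module screens classified 16S rRNA taxon-abundance tables
    for methanogen, anaerobic methanotroph (ANME), and aerobic methanotroph
    guilds, and synthetic-data generators provide ground-truthed fluid and
    taxonomy tables for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
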