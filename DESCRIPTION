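Package: dessonic
Title: Speed of Sound in Deep Eutectic Solvents from Molecular Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the speed of sound of deep eutectic solvents (DESs)
    from the molecular structures of their constituents alone. Pure-component
    critical properties and acentric factors are obtained with the modified
    Lydersen-Joback-Reid group-contribution scheme, combined into
    pseudo-component properties with the Lee-Kesler mixing rules, and fed to
    a four-coefficient corresponding-states correlation for the speed of
    sound. Includes four ionic-liquid literature models (Gardas-Coutinho,
    Hekayati-Esmaeilzadeh, Singh-Singh, and the atomic-contribution model of
    Haghbakhsh and co-workers), the Curl-Pitzer surface-tension formula, a
    packaged registry of 39 DESs with stored group decompositions, AARD/RD
    model evaluation, seeded coefficient refitting, a synthetic-data
    generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
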