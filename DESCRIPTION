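Package: octadrive
Title: Tetrad Analysis and Simulation of Supernumerary-Chromosome Meiotic
    Drive in Zymoseptoria tritici
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse the meiosis of the haploid wheat
    pathogen Zymoseptoria tritici, whose eight supernumerary (accessory)
    chromosomes segregate through eight-spore asci (octads). Provides a
    mechanistic cross simulator covering Mendelian segregation, a
    female-restricted meiotic drive, pre-meiotic amplification, preferential
    segregation and spore killing, together with chromosome loss and
    non-disjunction; ascus verification from core-marker ratios and
    twin-pair structure; per-ascus segregation-pattern classification
    (4:4, 4:0, 8:0, disomy, loss); exact binomial and Fisher/chi-squared
    drive statistics with one-spore-per-ascus randomisation; mechanism
    prediction and discrimination; and a SNP octad-sharing spectrum module
    with coverage filtering. All simulated tables round-trip through plain
    tab-separated files.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
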