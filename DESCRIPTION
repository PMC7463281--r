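Package: xdrive
Title: Population Genetics of a Driving Sex-Ratio X Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tidyverse-native tools for the population genomics and
    population genetics of a selfish (meiotically driving) Sex-Ratio X
    chromosome carrying a set of linked inversions. Implements pooled
    sequencing window statistics (pool-size-corrected methods-of-moments
    F_ST, PoPoolation-style pi and Tajima's D, consensus d_XY, site
    classification against an outgroup), F_ST-based divergence dating with
    per-window calibration, a self-contained Kingman coalescent with
    piecewise demography for inversion neutrality tests, haplotype-panel
    linkage disequilibrium with Fisher exact arrangement association,
    deterministic two-locus models of drive-selection-recombination
    dynamics on the X (gametic decay, haploid selection fitting, diploid
    recursion with balance-cost and invasion solvers), classical mapping
    and segregation statistics, and seeded synthetic-data generators for
    every input format.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    knitr,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
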