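Package: needlestoich
Title: Within-Branch C:N:P Stoichiometry and Nutrient Reallocation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecological stoichiometry of conifer needles and soils in
    nutrient-poor sandy plantations. Computes C:N:P mass ratios and five
    stoichiometric indices (homeostatic index, nutrient stress index, nutrient
    resorption efficiency, resorption priority index, stoichiometric deviation
    index) from apical/basal needle pairs and layered soil profiles; runs the
    variance-gated group-comparison chain (Levene, one-way or Welch ANOVA,
    Tukey HSD or Games-Howell, compact letter displays), Welch t-tests, a
    needle-soil Pearson correlation grid and a PCA of needle ratios; and ships
    a synthetic study-design generator with closed-form ground truth for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
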