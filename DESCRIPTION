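Package: gendineq
Title: Neighbourhood-Level Gender Inequality Indicators from Aggregate Census Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes dissemination-area (neighbourhood) gender inequality
    scores for twelve aggregate census indicators spanning five dimensions
    (demographic/household, education, income, work/leisure, political
    participation), tests whether the spatial variation of the scores
    exceeds pure sampling noise with a Monte Carlo homogeneous-inequality
    null, and compares inequality between and within geographic area types
    (metropolitan, mid-sized city, rural) using Kruskal-Wallis and
    Mann-Whitney rank tests, Spearman correlations, and population-weighted
    tertile stratification. A seeded synthetic aggregate-census generator
    with controllable between-neighbourhood heterogeneity and realistic
    data pathologies makes the whole pipeline testable without restricted
    census extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
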