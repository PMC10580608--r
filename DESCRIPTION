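Package: chclevels
Title: ACE-R to CHC Conversion and Rehabilitation Game Level Recommendation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts the five subscores of the Addenbrooke's Cognitive
    Examination Revised (ACE-R) into saturations of nine Cattell-Horn-Carroll
    (CHC) broad cognitive domains through an expert weighted-transfer matrix,
    and segments each saturation into one of six rehabilitation game difficulty
    levels. Provides two interchangeable surrogate predictors trained against
    the expert conversion: a 5-7-9 multilayer perceptron with staged-learning-rate
    online backpropagation, and a linguistic fuzzy rule base using evaluative
    expressions with perception-based logical deduction and defuzzification of
    evaluative expressions. Includes a statistical harness comparing predicted
    against expert-assigned levels (signed level-error tables, per-domain ANOVA
    and Kruskal-Wallis screens, Bonferroni all-pairwise comparisons) and a
    synthetic patient cohort generator emulating the demographic structure of a
    neurorehabilitation clinic population.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
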