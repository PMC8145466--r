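Package: dietadequacy
Title: Usual Micronutrient Intake and Probability of Adequacy from Repeated 24-h Recalls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for estimating the dietary adequacy of infants and young
    children (9-24 months) from repeated 24-h dietary recalls and a food
    composition table. Imputes breast-milk intake on breastfed child-days by
    the energy-gap method, estimates each child's usual nutrient intake with a
    Box-Cox random-intercept model (BLUE + BLUP prediction and bias-corrected
    back-transformation), classifies zinc and iron bioavailability from
    phytate molar ratios, and computes the probability of adequacy (PA) of
    fourteen micronutrients, mean PA, and nutrient densities by site and age
    period. Includes a synthetic-study generator with known ground truth for
    validation.
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
    yaml,
    lme4,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
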