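Package: dietshift
Title: Sandwich-Substitution Modeling of Nutrient Intake and Diet Quality
        in 24-Hour Recall Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Models the population-level consequences of swapping the
        sandwiches people actually report in 24-hour dietary recalls for
        prespecified composite sandwiches. Builds USDA-style food composites
        by proportional consumption weighting, removes typical-sandwich
        energy, nutrients and food-pattern equivalents from each person-day
        and injects a modeled profile, scores diet quality with the Healthy
        Eating Index 2010, and estimates survey-weighted population means
        with Taylor-linearized standard errors for stratified two-PSU
        designs and a 99% confidence-interval non-overlap decision rule.
        Ships the five modeled sandwich profiles as a fixture and a
        synthetic NHANES-like population generator so the whole pipeline is
        testable without survey downloads.
License: MIT
Encoding: UTF-8
Imports: stats, utils, foreign, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
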