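Package: mpowersim
Title: Abridged Tobacco-Control Policy Simulation for MPOWER Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a single-baseline-year (abridged) tobacco-control
    policy simulation in the SimSmoke family. From a country profile (adult
    population and smoking prevalence by gender, labor statistics) and the
    current status of the six WHO MPOWER policy domains, the model computes
    per-policy and combined short-term (5-year) and long-term (40-year)
    relative reductions in smoking prevalence from full MPOWER
    implementation, and projects reductions in the number of smokers and in
    smoking-attributable deaths among current smokers. Includes interval
    sensitivity analysis over the published effect-size ranges, a YAML
    country-configuration reader, a synthetic country-profile generator for
    property testing, and a packaged Israel 2014 profile.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
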