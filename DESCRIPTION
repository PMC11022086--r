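Package: cvdprev
Title: Markov Cohort Cost-Effectiveness Model of Cardiovascular Disease
    Screening and Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A nine-state Markov cohort model of cardiovascular disease
    (CVD) screening, primary prevention, and secondary prevention for a
    low-resource health system, with Myanmar as the default setting.
    Provides deterministic cost-effectiveness analysis (efficiency
    frontier, incremental cost-effectiveness ratios, net monetary
    benefit), probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, subgroup analysis by sex and starting age, and
    a budget impact analysis, together with a packaged default parameter
    set, a parameter-file schema (YAML/CSV), and synthetic-data
    generators for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
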