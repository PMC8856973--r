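Package: concx
Title: Concentration Curves for Wealth-Related Inequality in NCD Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds concentration tables and concentration curves relating
    ordered wealth categories to ordered exposure categories for modifiable
    risk factors of non-communicable diseases (alcohol use, tobacco use,
    unhealthy diet, physical inactivity), in the style of DHS-type survey
    analyses. Provides the 45-degree line of perfect equality, a trapezoid
    concentration index with bootstrap percentile intervals, curve dominance
    classification, a synthetic survey generator with configurable
    quintile-conditional exposure scenarios, a record recoding/filtering
    pipeline with audit counts, and an end-to-end reporting pipeline with
    figures and machine-readable manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
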