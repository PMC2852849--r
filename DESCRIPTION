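Package: terescore
Title: Theoretical Efficacy Scoring of Estrogen-Mimicking Compound Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes receptor-affinity-weighted additive potency scores for
    formulations of estrogen-mimicking compounds such as soy and red-clover
    isoflavones. Each compound's daily intake is weighted by its relative
    binding affinity (percent of estradiol) at the alpha and beta estrogen
    receptors to give a Theoretical Efficacy (TE) and its expression relative
    to estradiol (TERE, written 1/x), together with a risk/benefit partition
    across receptor subtypes, the absolute alpha-receptor load, and a
    bioactivity-relevance classification. Includes aglycone-equivalent dose
    conversion for glycosylated and acylated conjugates, a packaged default
    affinity table, multi-formulation comparison reports, CSV/YAML readers and
    writers, fixture generation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
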