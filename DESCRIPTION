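Package: ebfemr
Title: Exclusive Breastfeeding Ascertainment from Primary-Care EMR Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based ascertainment of infant feeding practices from
    well-baby visit notes in primary-care electronic medical records.
    Provides a synthetic EMR corpus generator with known ground-truth
    feeding trajectories, a lexicon-driven free-text search algorithm that
    detects Rourke Baby Records and classifies per-visit feeding status,
    longitudinal inference of exclusive breastfeeding at 2, 4 and 6 months
    of age (including inference from future visits), and the associated
    epidemiological statistics: rates, rate ratios with Katz log-transform
    confidence intervals, standardized differences and Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
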