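Package: topoquant
Title: Topoisomer Ladder Densitometry and DNA Supercoiling Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies plasmid DNA supercoiling from agarose/chloroquine gel
    lane profiles. Detects topoisomer bands, assigns integer apparent linking
    numbers (Lk), computes intensity-weighted mean Lk per lane, and normalizes
    across gels to Relative Supercoiling Units (RSU) against a pair of
    reference lanes. Scores DNA gyrase activity as the change in weighted mean
    Lk per hour with percent variation against a no-polyamine baseline, and
    compares groups by Student/Welch t-tests or Tukey's HSD with a compact
    letter display computed from the studentized range distribution. Also
    includes HPLC standard-curve calibration of polyamines with conversion to
    intracellular concentration from CFU counts and cell volume, free-fraction
    estimates, detection-limit censoring, and log2 fold-change analysis of
    FPKM expression tables. A synthetic gel-lane generator with known ground
    truth makes every stage testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    zoo,
    pracma,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
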