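Package: trem2quant
Title: Multi-Modal Quantitative Analysis for Trem2 H157Y Mouse Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested, reusable re-implementation of the quantitative analyses
    used in multi-modal mouse studies of TREM2 biology: field-potential feature
    extraction (fEPSP slope, fiber volley, input-output curves, paired-pulse
    facilitation, LTP profiles), first-order interstitial-fluid amyloid-beta
    clearance kinetics from in vivo microdialysis, histological plaque and
    microglial morphometry from calibrated fluorescence images, stable-isotope
    internal-standard targeted-proteomics quantitation of soluble versus
    full-length TREM2, post-count RNA-seq differential-expression and
    co-expression module analysis with permutation module preservation, and a
    study-style group-statistics decision rule. A synthetic-data generator with
    known ground truth makes every stage verifiable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    edgeR,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
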