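Package: fbconn
Title: Filter-Banked Connectivity for Time-Varying Functional Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates time-varying functional network connectivity by frequency
    tiling directly in the connectivity domain. A per-sample normalized product
    trajectory w(t) is computed for every component pair and decomposed by a bank
    of stable zero-phase IIR band filters covering 0 to Nyquist, generalizing
    sliding-window Pearson correlation (whose rectangular window is the low-pass
    special case). Includes k-means connectivity-state clustering with per-band
    fraction-rate frequency profiles, two-group comparison with false discovery
    rate control, and a multivariate-normal simulator with oscillating,
    state-switching covariance for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
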