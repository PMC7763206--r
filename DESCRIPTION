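Package: anxsig
Title: Anxiety Level Estimation from Electrodermal and Heart-Rate Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating a subject's anxiety level in real time from
    skin conductance (electrodermal activity) and heart rate recorded during
    virtual-reality exposure sessions. Implements aliasing-aware FIR low-pass
    filtering and decimation, continuous decomposition of skin conductance into
    tonic and phasic components with skin-conductance-response event detection,
    event-locked 5-second windowing, a 32-feature set spanning time, event and
    frequency domains, a second-order polynomial regression estimator selected
    by exhaustive feature-subset search, and threshold classification into two
    or three anxiety classes. A seeded synthetic-session generator emulates the
    physiological ranges of electrodermal and cardiac activity so the whole
    chain can be exercised and validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
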