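Package: selstopsig
Title: Simulation and Analysis Pipeline for the Selective Stop-Signal Task with ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for selective stop-signal
    experiments with concurrent EEG: generation and validation of the 700-trial
    reactive/proactive task schedule, behavioural simulation under an
    independent horse-race model (ex-Gaussian go process, Gaussian stop
    process, proactive slowing), synthetic multichannel EEG containing the
    canonical cue/go/stop event-related potential components (P3-cue, P3-Go,
    N2-stop, P3-stop) plus blink and gross artifacts, behavioural scoring
    including integration-method SSRT, ERP conditioning (band-pass filtering,
    epoching, amplitude rejection, ICA-based blink zeroing, grand averaging,
    windowed peak measurement), and the group-level statistics (independent
    t-tests, mixed repeated-measures ANOVA with partial eta squared and
    Bonferroni-adjusted follow-ups).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
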