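Package: meafdr
Title: Stimulus-Evoked Functional Connectivity in Cultured Neuronal
    Networks via Local False Discovery Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the temporal evolution of functional connectivity
    in dissociated cortical cultures grown on micro-electrode arrays
    (MEAs). Stimulus-evoked spike counts in configurable post-stimulus
    windows are normalized by matched spontaneous activity to form a
    per-day stimulated-by-recording response matrix; significant
    stimulus-response electrode pairs are selected with an empirical-Bayes
    local false discovery rate procedure (two-group mixture model with
    estimated non-null proportion, null scale and kernel marginal
    density); significant pairs define a directed connectivity graph whose
    mean connection length and hub ("supernode") counts are tracked over
    days in vitro and compared within and across culture batches by
    one-way ANOVA with Tukey multiple comparisons. Includes a synthetic
    MEA data generator (bursting spontaneous activity, latency-structured
    evoked responses, two-phase network growth, batch structure) so the
    entire pipeline is testable without laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
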