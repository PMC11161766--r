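Package: phasecode
Title: Oscillatory Phase Coding of Spoken-Word Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and statistical analysis of phase-dependent speech
    categorization. Implements a two-level oscillation-modulated
    threshold-node model (an extension of the STiMCON architecture) in which
    word and phoneme representations with frequency-dependent sensitivity
    are activated at different phases of an ongoing theta oscillation, plus
    the complete analysis chain used to detect such phase codes in behavior
    and in region-of-interest neural time series: demeaned fixed-frequency
    sinusoid fits with permutation nulls, Morlet time-frequency phase
    extraction, logistic regression on sine/cosine of prestimulus phase,
    cluster-based permutation statistics, circular means, directed v-tests,
    and product-combined probabilities. Ships synthetic-data generators that
    emulate the psychophysics and MEG designs so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
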