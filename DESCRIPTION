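Package: hmdbn
Title: Time-Varying Gene Regulatory Network Inference with Hidden Markov
    Dynamic Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns node-specific, non-stationary dynamic Bayesian networks
    from discrete gene-expression time series. Each gene's parent set is
    allowed to change over time by treating the candidate parent-set
    configurations ("hidden graphs") as the hidden states of a hidden Markov
    model; a structural EM search with a Baum-Welch-weighted BIC score
    (BWBIC) recovers the time-varying topology and the transition times at
    which regulatory inputs change. Includes scaled forward-backward and
    Viterbi engines, expected-count multinomial CPD estimation, hard-segment
    BIC and BDe baseline scores, a benchmark simulator for time-varying
    networks, and a per-observation precision/recall evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
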