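Package: reliwalk
Title: Quantum and Markov Random-Walk Models of Evolving Reliability Judgements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the block-by-block evolution of a human participant's
    judgement of an AI system's reliability as a random walk over a discrete
    reliability scale, under two dynamics: a continuous-time Markov
    birth-death chain driven by an intensity matrix, and a quantum walk
    driven by Hamiltonian (Schroedinger) evolution with Born-rule readout,
    including a corner coupling between the extreme reliability states.
    Ships a synthetic Wizard-of-Oz experiment generator (trial logs,
    damped-oscillation reliability ratings, event-locked EEG epochs with a
    condition-dependent P3-like component), a simplified event-related
    potential pipeline (trial rejection, baseline correction, condition
    averaging, difference waves, peak latencies), and RMSE-based model
    comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
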