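Package: driftnet
Title: Representational Drift in a Recurrent Rate Network with Fluctuating Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a rate-based recurrent neural network in which slowly
    fluctuating intrinsic excitability biases Hebbian plasticity, so that the
    neural ensemble encoding a memory drifts across days while remaining
    decodable. Provides the multi-day stimulation protocols (single ensemble,
    two contexts, excitability-amplitude sweeps), correlation-based temporal
    decoders (day decoder, ordinal time decoder with a permutation null and
    t-statistic, drift rate), a homeostatically normalized Hebbian read-out
    neuron with a quality index, and seeded experiment drivers that regenerate
    every simulated result from a configuration and a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml
Config/testthat/edition: 3
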