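Package: satpomdp
Title: Optimal Control of Attention in a Sustained Attention Task POMDP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative model of costed attentional control in the rodent
    sustained attention task (SAT). Trials in which a brief signal may arrive
    at an uncertain time are modelled as a partially observable Markov
    decision process whose latent stage is pre-signal, signal-on or
    post-signal, and whose agent chooses between weak and strong attention;
    strong attention lowers observation noise but incurs a switch cost and a
    maintenance cost. The package provides the trial generative model, exact
    Bayesian belief filtering, belief-grid discretization with barycentric
    interpolation, finite-horizon backward induction for single trials,
    average-reward planning over continuing trials with cross-trial carry-over
    of the attentional state, Monte-Carlo simulation with signal-detection
    summaries (hit and false-alarm rates, d'), optogenetic-style
    match/mismatch experiments, parameter sweeps with attentional breaking
    points, and sessions with nonstationary estimated signal probability that
    yield baseline-corrected phasic acetylcholine proxies.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
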