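Package: turingnets
Title: High-Throughput Screening of Turing Reaction-Diffusion Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exhaustive enumeration and linear stability analysis of small
    signaling networks with diffusible and non-diffusible (cell-autonomous)
    nodes. Enumerates all minimal N-node networks with k first-order
    interactions, filters them by strong connectivity and isomorphism,
    decides by sampling which signed topologies admit diffusion-driven
    (Turing) instability, classifies the diffusivity requirements of each
    network (Type I: differential diffusivity required; Type II: equal
    diffusivities allowed; Type III: any positive diffusivities), predicts
    in-phase/out-of-phase relations of the emerging periodic patterns,
    estimates robustness as the relative volume of the Turing space, and
    confirms predictions with finite-difference reaction-diffusion
    simulations in one and two dimensions. Screens can be constrained with
    qualitative and quantitative experimental data (fixed interaction signs
    or rates, forbidden edges, diffusion ratios, required phase relations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
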