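Package: denovolearn
Title: Gradient-Free De Novo Learning of Goal-Directed Generative Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows, reduces and deploys hierarchical discrete generative
    models (generalised partially observed Markov decision processes) directly
    from streams of one-hot categorical observations, with no gradients and no
    pre-specified state space.  Structure is discovered by mutual-information
    channel grouping and lossless compression of grouped outcome sequences
    into unique states and paths; parameters are Dirichlet counts accumulated
    under reward-gated active learning; Bayesian model reduction retains only
    states inside the basins of attraction of goal states until a pullback
    attractor (a closed orbit of mutually reachable goal states) emerges.
    The resulting model plays by inductive (backward-induction) active
    inference, realising proprioceptive predictions as actions.  A bundled
    arcade game (12 x 9 pixel grid, 111 one-hot observation channels) serves
    as the generative process, so the whole pipeline is exercisable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
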