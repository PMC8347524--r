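Package: rnafoldpath
Title: Learning RNA Secondary-Structure Folding Paths by Self-Play Tree Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Folds an RNA secondary structure one base pair at a time inside a
    reinforcement-learning environment, guided by a dual-head policy/value
    convolutional network and a prior-weighted Monte Carlo tree search, and
    extracts the most probable ("fastest") folding path from the accumulated
    episode trajectories. Includes dot-bracket/bpseq/CT structure I/O with
    pseudoknot layers, a legality-pruned base-pair action space, a self-play
    trainer with a FIFO replay buffer and error-balanced multi-RNA sampling,
    and folding-path tree analysis (modal path, near-native filtering,
    pair-formation order maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
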