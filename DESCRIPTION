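Package: msgcascade
Title: Agent-Based Simulation of Message Cascades in Online Social Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates how a single message spreads through an online social
    network of agents endowed with latent affective and cognitive attitudes.
    Agents notice a message when its affective stimulus exceeds a personal
    noticing threshold and forward it when a dual-process evaluation (the
    geometric mean of an affective and a cognitive process value) exceeds a
    posting threshold. Thresholds are either drawn uniformly at random or
    derived from Big Five personality traits sampled from a correlated
    multivariate normal distribution. Provides six network environments
    (Erdos-Renyi, Barabasi-Albert, Watts-Strogatz, static scale-free,
    stochastic block model, and SNAP-format edge lists such as the
    ego-Facebook network), structural metrics, a synchronous cascade engine,
    a seeded Monte-Carlo replication harness, a general-linear-model analysis
    of final spread, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
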