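Package: airnet
Title: Aerial Connectivity Networks from Backward Air-Mass Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers long-distance aerial connectivity between regions from
    48-hour backward air-mass trajectories. Builds daily directed contact
    networks over a spatial grid, aggregates them over arbitrary day subsets
    (yearly, monthly, seasonal), and characterizes the resulting weighted
    digraphs with effective-distance shortest paths, density, weighted
    transitivity and strength correlation. Provides cut-distance comparison
    of same-node-set networks (exact enumeration and a genetic algorithm),
    hierarchical seasonal clustering of monthly networks, Pareto-front
    selection of edges that jointly maximize weight and geographical
    distance, seven node-relevance indices, and a deterministic threshold
    susceptible-infected epidemic model yielding spreader (SI persistence)
    and receptor (SI frequency) indices. Includes a synthetic trajectory
    generator with season-dependent wind regimes so the full pipeline runs
    without external meteorological data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    geosphere,
    mgcv,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
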