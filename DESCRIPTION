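Package: tunnelscape
Title: Identification and Clustering of Transport Tunnels in Protein
    Structure Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometry-based detection, characterization and clustering of
    transport tunnels and channels in static protein structures and in
    aligned conformational ensembles such as molecular dynamics snapshots.
    Structures are approximated by equal-radius balls, tunnels are found as
    lowest-cost paths on the Voronoi diagram of the ball centers, pathways
    from all snapshots are clustered by average-link hierarchical clustering
    of weighted axis descriptors (with a sampled clustering plus k-nearest
    neighbour scale-out for very large pathway sets), and ranked collective
    tunnels are reported with bottleneck, profile, throughput and
    residue-level statistics, heat maps and PyMOL/VMD visualization scripts.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    parallel,
    grDevices,
    graphics,
    Rcpp,
    igraph,
    bio3d,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    class,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
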