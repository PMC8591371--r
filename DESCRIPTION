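Package: fvconn
Title: Static and Dynamic Brain Network Analysis for Free-Viewing fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and characterizes macaque whole-cortex brain networks from
    regional BOLD time series and diffusion streamline counts. Functional
    (free-viewing) networks are wavelet band-limited absolute-correlation
    matrices thresholded by false discovery rate; structural networks are
    streamline-count matrices filtered and log-scaled. The package provides
    graph characterization (density by hemisphere, degree and its
    complementary CDF, clustering, characteristic path length,
    degree-preserving rewired nulls, edge-distance profiles), multiresolution
    consensus modularity, eigenvector-centrality hub detection, time-varying
    connectivity by multiplication of temporal derivatives with epoch-averaged
    network states, structure-function comparison, and a synthetic-data
    generator with planted modules and epoch-specific hubs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    mclust,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
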