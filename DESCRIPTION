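Package: mlinet
Title: Identifying Influential Spreaders in Temporal Networks by Neighborhood Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking nodes of temporal (snapshot-sequence) contact
    networks by their spreading influence. Implements the MLI method: each
    node's temporal neighborhood is embedded into a fixed-size feature matrix
    and a small convolutional regressor, trained on infected scales from a
    discrete-time SIR model, predicts node influence. Also provides the
    temporal SIR simulator that defines ground truth, five benchmark temporal
    centralities (closeness, betweenness, k-shell, degree deviation, and
    dynamics-sensitive centrality), time-respecting shortest-path machinery,
    a synthetic temporal scale-free network generator, and a Kendall-tau /
    hitting-rate evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
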