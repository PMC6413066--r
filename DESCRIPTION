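Package: elcksvd
Title: Kernelized Label-Consistent K-SVD for Electronic-Nose Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discriminative dictionary learning for gas-sensor-array
    (electronic-nose) classification. Implements orthogonal matching
    pursuit, K-SVD dictionary learning, label-consistent K-SVD with a
    normalized three-term objective (reconstruction, discriminative
    sparse-code, and classification error), an RBF empirical kernel map
    so the dictionary is learned in a high-dimensional feature space,
    and quantum-behaved particle swarm optimization (PSO/QPSO/EQPSO) of
    the objective weights, kernel scale, and a binary sensor-selection
    mask. Ships a synthetic metal-oxide sensor response generator
    emulating a baseline/injection/recovery sampling protocol with
    cross-sensitive sensors and nonlinear class structure, plus an
    extreme learning machine for plain K-SVD sparse codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
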