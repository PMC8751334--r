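Package: phiclust
Title: Random-Matrix Clusterability Measure for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies whether the variability inside a cluster of cells is
    consistent with random noise or carries deterministic sub-structure.
    The expression matrix is modelled as a random matrix perturbed by a
    low-rank noise-free signal; singular values exceeding the
    Marchenko-Pastur bulk (gated by a Tracy-Widom threshold and a
    Shapiro-Wilk normality test on the singular vectors) are mapped by
    low-rank perturbation theory to the squared cosine between measured and
    noise-free singular vectors. The largest of these, phiclust, lies in
    [0, 1) and is a parameter-free proxy for the theoretically achievable
    clustering quality. Includes confounder regression on singular vectors,
    resampling-based uncertainty, a gene-space conjugate (g-phiclust),
    variance-driving gene ranking, gamma-Poisson and planted-signal
    simulators, and a Bayes-classifier oracle (tARI/tSIL) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
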