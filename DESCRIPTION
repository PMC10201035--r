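Package: dockselect
Title: Per-Instance Algorithm Selection for Protein-Ligand Docking Portfolios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-based per-instance algorithm selection for portfolios of
    stochastic protein-ligand docking solvers. Ingests AutoDock DLG logs or
    long-format run tables, aggregates repeated docking runs into AVG/BEST
    performance matrices, rank-transforms them, and fits an ALORS-style
    selector: truncated SVD of the instance-by-algorithm rank matrix plus a
    random-forest regression from molecular-descriptor and substructure-
    fingerprint features onto the instance latent factors. Includes tenfold
    cross-validated evaluation against single-best, virtual-best and random
    baselines, feature-importance and portfolio-reduction analyses,
    instance-space embedding and clustering, and a synthetic docking
    benchmark generator with planted algorithm complementarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    cluster,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
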