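Package: gapdca
Title: Gap-Aware Direct Coupling Analysis for Protein Contact Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pseudo-likelihood inference of Potts models from protein multiple
    sequence alignments for residue-residue contact prediction, including a
    gap-extended model (gplmDCA) with parameters for maximal gap runs, the
    gap-excluded scoring variant (plmDCA20), average-product-corrected
    Frobenius coupling scores, coupling decimation, sequence reweighting,
    Gibbs sampling of synthetic alignments from known models, and a
    benchmarking harness computing positive predictive value against
    structural contact maps extracted from PDB files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    Biostrings,
    bio3d,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
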