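Package: argphos
Title: Arginine-Phosphate Interactions and Re-Entrant Condensation of
    Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Metropolis Monte Carlo modelling of the
    intrinsically disordered saliva protein histatin 5 in the presence of
    explicit polyvalent anions (citrate, pyrophosphate, tripolyphosphate),
    including a short-ranged arginine-phosphate attraction term, together
    with the analyses used to characterise re-entrant condensation:
    Guinier and Kratky analysis of small-angle X-ray scattering curves,
    condensation/decondensation boundary detection from precipitation
    series, the linear phase-boundary relation giving the number of bound
    ions per protein, ionic-strength and NaCl-equivalence calculations,
    and synthetic-data generators with known ground truth for validating
    the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
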