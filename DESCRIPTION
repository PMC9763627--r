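Package: rbcbridge
Title: Cross-Bridge Migration Model of Red Blood Cell Doublet Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deformable two-cell simulator of plasma-mediated red blood cell
    (RBC) doublet aggregation and forced disaggregation. Inter-cell adhesion
    arises from specific and non-specific fibrinogen cross-bridges modelled by
    a Morse-type potential on triangulated membrane meshes; the density of
    mobile cross-bridges evolves on each deforming cell surface by a
    convection-diffusion equation with friction-induced drift (the cross-bridge
    migration model, CBMM). Includes a coarse-grained viscoelastic membrane
    model, intercellular Couette friction, doublet-formation and
    optical-tweezers disaggregation protocols, and CSV/VTK/JSON writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
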