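Package: shapescape
Title: Building and Visualising Morphospaces for Landmark and Outline Shape Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for geometric morphometrics centred on the construction
    and layered visualisation of morphospaces. Provides generalized Procrustes
    alignment, thin-plate spline interpolation and elliptic Fourier transforms
    as the geometric substrate; refinement of shape data by linear-model
    detrending and Burnaby orthogonal projection; six ordination families
    (PCA, between-groups PCA with leave-one-out cross-validation, two-block
    partial least squares, Burnaby ordination, phylogenetic PCA and
    phylogenetically aligned component analysis); a morphospace canvas with
    regularly spaced background shape models onto which shapes, groups,
    morphometric axes, phylogenies, performance landscapes and Pareto fronts
    can be projected; hybrid shape-versus-covariate views and phenograms; and
    deterministic synthetic-data generators for group-structured, longitudinal
    and comparative (Brownian motion) shape datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    phytools,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
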