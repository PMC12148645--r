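Package: SAFTractometry
Title: Short Association Fiber Tractometry and Developmental Microstructure Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies short association fibers (SAFs, U-fibers of 5-40 mm)
    relative to long-range white-matter bundles by proximity to binary bundle
    masks, with MDF/QuickBundles clustering and ladder-score outlier rejection,
    and characterizes bundle microstructure over development. Includes a
    synthetic phantom and cohort generator with known ground truth, a
    restricted (b <= 1500 s/mm^2) log-linear diffusion-tensor fit with
    FA/MD/AD/RD scalars, iteratively reweighted least-squares robust
    regression with the Tukey bisquare weight for age/sex/TICV models of
    z-normalized bundle features, partial inter-feature correlations, and a
    Fisher-z specificity test of associated SAF-LR coupling, all with
    Benjamini-Hochberg FDR control. Feature tables are stored as
    SummarizedExperiment objects; tractograms round-trip through TCK and TRK
    and masks through NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
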