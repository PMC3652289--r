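Package: nodulecad
Title: Computer-Aided Detection of Pulmonary Nodules in CT by Fuzzy Active
    Contours and Mixture-Model Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computer-aided detection (CAD) chain for pulmonary
    nodules in chest CT. Candidate lesions are segmented with a fuzzy
    integrated active contour model that combines a posterior-probability
    edge-stopping function, region-scalable local intensity fitting and a
    fuzzy membership field built from the volumetric shape index. Candidates
    attached to vessels are refined with a hybrid parametric mixture model
    (multivariate Gaussians plus a uniform outlier component) over intensity,
    membership and structure-tensor flow-direction observations. Surviving
    candidates are described by a 21-descriptor feature catalogue and
    classified by a knowledge gate followed by a cost-sensitive support
    vector machine tuned by cross-validated AUC grid search. A synthetic CT
    phantom generator with solid, part-solid and nonsolid (ground-glass)
    nodules, tubular vessels, juxtavascular attachments, noise and a smooth
    bias field provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
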