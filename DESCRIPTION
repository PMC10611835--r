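Package: fetagree
Title: FET PET Tumour Volume Delineation, Dynamic Analysis and
    Inter-Observer Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for semi-automatic biological tumour volume (BTV)
    delineation on amino-acid PET of glioma, following the
    crescent-background, tumour-to-background-ratio (TBR) thresholding
    workflow used in multi-centre trial credentialing: background
    assessment from a crescent-shaped contralateral volume of interest,
    TBR thresholding of a spherical search region, audited manual mask
    editing, TBR statistics, time-activity-curve extraction and
    classification from dynamic frames, and a clinical interpretation
    rule table.  Inter-observer agreement is quantified with the
    coefficient of variation, pairwise Dice/Jaccard overlap, Hausdorff
    and mean absolute surface distances, and the two-way
    absolute-agreement single-rater intraclass correlation ICC(2,1)
    with F-based confidence intervals.  A synthetic brain phantom and a
    simulated multi-rater contouring cohort make every stage testable
    without patient data, and credentialing review records can be
    tabulated into pass-rate and violation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
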