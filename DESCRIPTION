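Package: graftquant
Title: Serial Cone-Beam CT Volumetry of Mandibular Bone Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bone-graft volume change from serial cone-beam CT
    (CBCT) in paired internal-control designs. Provides rigid registration of
    follow-up to baseline volumes, per-scan intensity normalization (CBCT
    units are not calibrated Hounsfield units), exclusion masking of the host
    mandible and metal hardware, threshold-driven curvature-regularized
    level-set segmentation of grafted bone, largest-connected-component
    volume-of-interest extraction, and the paired statistics of an
    internal-control trial (per-graft changes, group summaries, paired t
    test, Cohen's d). A digital phantom generator simulates paired scans of
    a mandible-angle scene with known ground-truth graft volumes for
    validation. Reads and writes MetaImage and NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
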