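Package: tle4d
Title: Target Localization Error and Tracking Margins from 4D-CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the target localization error (TLE) that arises in
    dynamic tumor-tracking radiotherapy when lung tumors and implanted
    fiducial markers move asynchronously across respiratory phases.  From
    per-phase gross tumor volume (GTV) masks and fiducial-marker
    coordinates, the package enumerates marker combinations, aligns each
    phase on the marker centroid, computes per-direction root mean square
    errors of the GTV centroid, and pools their 95th percentile into
    anisotropic TLE margins.  It also constructs union-of-shifted-GTV
    targets, margin-expanded reference targets, and geometric coverage
    metrics for validating the derived margins, and ships a synthetic
    4D respiratory phantom generator with analytic ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
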