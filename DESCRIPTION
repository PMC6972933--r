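Package: vofseg
Title: Virtual Dissection and Endpoint Connectomics of the Vertical Occipital Fasciculus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Atlas-constrained virtual dissection of the vertical occipital
    fasciculus (VOF) from whole-brain tractograms: two-ROI endpoint selection
    over dorsal, ventral and lateral-occipital parcel groups, superior-inferior
    orientation classification, region-of-avoidance exclusion, and
    relative-position filtering against reference bundles (lateral to the
    inferior longitudinal fasciculus, posterior to the arcuate fasciculus).
    Downstream endpoint analysis builds parcel-by-parcel connectivity matrices,
    endpoint-projection and connection ratio tables, tract volume and mean
    fractional anisotropy, hemispheric laterality indices with paired
    t-statistics, and connectogram table export. A fully synthetic hemispheric
    phantom generator with configurable multinomial endpoint statistics makes
    the whole pipeline testable without imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
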