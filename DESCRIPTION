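Package: ulnadiff
Title: Bilateral Ulnar Length Differences from 3D Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the bilateral (left-right) length difference of the
    ulna from triangulated 3D surface meshes, following the standardized
    mirror-align-measure workflow used in 3D planning of corrective
    osteotomies for distal radius malunion: the left ulna is mirrored and
    rigidly aligned to the right ulna from proximal to distal (iterative
    closest point), the longer ulna is cut halfway between the olecranon
    tip and the ulnar dome tip, a circle is fitted to the cut contour,
    and the length difference is projected onto the axis from the fitted
    circle centre to the dome tip. Includes STL/PLY mesh input/output, a
    parametric synthetic-ulna and cohort simulator with exact ground
    truth, and the accompanying cohort statistics: observer adjudication,
    intraclass correlation, subgroup t-tests, Kolmogorov-Smirnov
    normality checks, and sample-size calculation for a mean.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
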