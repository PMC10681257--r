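Package: facesym
Title: Landmark-Free Midsagittal Plane Construction and Asymmetry Mapping
    for 3D Facial Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies bilateral symmetry of 3D surface meshes (facial
    stereophotogrammetry scans and similar single-valued surfaces) without
    anatomical landmarks.  A mesh is duplicated and mirrored, the mirrored
    copy is best-fit approximated to the original by point-to-plane
    iterative closest point registration with exact closest-point search,
    and the midsagittal plane is constructed by principal component
    analysis of the midpoints of all segments joining index-corresponding
    contralateral vertices.  Per-vertex closest-point distance maps, mean
    absolute distance (MAD) statistics over selected measurement areas,
    colour-coded mesh exports, a synthetic face generator with known
    ground-truth symmetry, and a reproducibility protocol based on
    re-superimposition from perturbed poses are included, together with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
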