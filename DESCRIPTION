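Package: leafgas
Title: Leaf Mesophyll Diffusion Anatomy and Gas Exchange Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools linking 3D leaf anatomy to photosynthetic gas exchange.
    Computes mesophyll diffusion traits (porosity, tortuosity, lateral path
    lengthening, intercellular-airspace conductance) from segmented microCT
    label volumes via exact distance transforms and geodesic shortest-path
    propagation; estimates mesophyll conductance and chloroplast CO2 from
    combined gas exchange and 13C discrimination records; fits
    Farquhar-von Caemmerer-Berry A-Ci curves; derives leaflet hydraulic
    conductance and anatomical maximum stomatal conductance; and extracts
    normalized chlorophyll-fluorescence depth and bundle-sheath-extension
    proximity profiles from cross-section images. Includes seeded synthetic
    generators (leaf phantoms, forward-simulated isotope records,
    fluorescence images, A-Ci curves) with exactly recomputable ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    png
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
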