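Package: leafcontrast
Title: Avian Photoreceptor Contrast Between Upper and Lower Leaf Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Radiometric modelling and image-based analysis of the contrast
    between upper and lower leaf surfaces as seen by avian photoreceptors.
    Provides visual-pigment and oil-droplet spectral templates, receptor
    quantum catches, Michelson and receptor-noise-limited (JND) contrasts,
    a Monte-Carlo optical model of leaf radiances in vegetated habitats
    (diffuse and specular components under sun, sky, cloud and canopy
    illumination), paired sign tests for multispectral pixel-selection
    datasets, and a synthetic-data module that generates leaf, litter,
    illumination and camera spectra plus selection datasets so the full
    pipeline runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
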