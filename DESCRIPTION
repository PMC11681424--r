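Package: papunmix
Title: Multispectral Dye-Amount Unmixing for Papanicolaou-Stained Cytology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies per-dye stain amounts in multispectral microscope
    images of Papanicolaou-stained cytology specimens. Converts multi-band
    intensity stacks to absorbance under the Lambert-Beer law, calibrates a
    stain matrix from single-stain specimens, unmixes per-pixel amounts of
    hematoxylin, eosin Y, light green SF and orange G via the Moore-Penrose
    pseudo-inverse, normalizes amounts against reference values, masks
    unstained background, and classifies mucin patches as endocervical (EC)
    or lobular endocervical glandular hyperplasia (LEGH) with Fisher linear
    discriminants. Includes an sRGB rendering path for visual QC and a
    synthetic phantom generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
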