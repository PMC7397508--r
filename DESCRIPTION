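Package: hepaquant
Title: Automated Quantitation of NAFLD Histology on H&E and Sirius Red Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated quantitation of the four key histologic features of
    nonalcoholic fatty liver disease from brightfield photomicrographs of liver
    biopsy sections. Segments fat vacuoles, inflammatory infiltrate and
    ballooned hepatocytes on hematoxylin-eosin images and collagen on
    picrosirius-red images, expresses each as a percentage of tissue area
    (including the collagen proportionate area after structural-collagen
    exclusion), combines the percentages into a published NASH score with
    fibrosis bands, and provides the agreement statistics (ICC, weighted kappa,
    Jonckheere-Terpstra trend, ROC) used to validate quantitative histology
    against semiquantitative NASH CRN scoring. Includes a seeded synthetic
    histology generator with exact ground-truth masks so the whole pipeline is
    testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    pROC,
    png,
    ranger,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
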