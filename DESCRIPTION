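Package: radbiodose
Title: Cellular and Small-Animal Dosimetry for Alpha- and Beta-Emitting
    Radiopharmaceuticals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing alpha-emitting (astatine-211) and
    beta-emitting (iodine-131) radiopharmaceuticals in vitro and in vivo.
    Provides embedded decay data, a Monte Carlo estimator of cellular
    S-values (absorbed dose per decay) for the coaxial-cylinder
    dish/cell-layer/solution geometry of radionuclide-exposure assays,
    absorbed-dose calculation for in vitro treatments, quantification of
    DNA double-strand-break induction from two-channel fluorescence
    images, linear and linear-quadratic clonogenic survival fitting with
    iso-effect doses and relative biological effectiveness, MIRD-style
    biodistribution dosimetry with tumour-growth summaries, and seeded
    synthetic-data generators so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
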