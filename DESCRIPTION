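Package: tracheapat
Title: Simulated Photoacoustic Tomography and Morphometry of Tracheal Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A synthetic-data pipeline for photoacoustic evaluation of
    tracheal stenosis. Generates parametric digital trachea phantoms for
    four experimental groups (normal, mucosal edema, granulomatous
    hyperplasia, cicatricial scar), simulates band-limited photoacoustic
    signals on a 128-element concave arc transducer, reconstructs
    cross-sectional images by universal back-projection, performs
    per-pixel non-negative spectral unmixing into hemoglobin, collagen
    and water maps, and measures tracheal wall thickness, lumen
    cross-sectional area and stenosis rate together with inter-observer
    agreement (Pearson, Bland-Altman) and between-group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    EBImage,
    tiff,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
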