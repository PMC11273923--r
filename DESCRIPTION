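Package: agenas
Title: Neural Architecture Search for Dental Age Estimation from Panoramic Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for searching, building and evaluating compact convolutional
    networks that estimate chronological age from orthopantomograms (dental
    panoramic radiographs). Provides a differentiable cell-based search engine
    with partial channel connections and edge normalization, a single-path
    one-shot supernet engine over a 16-layer MobileNetV2-style space with a
    parallel asymmetric convolution block, builders for the searched AGENet and
    AGE-SPOS architectures, an expected-value (DEX) age head over 76 age bins,
    analytic multiply-accumulate and parameter accounting with closed-form block
    costs, evaluation metrics (MAE, cumulative score, per-decade MAE), and a
    deterministic synthetic pseudo-radiograph generator so that every stage is
    exercisable without clinical data. Includes a compact reverse-mode layer
    library (im2col convolutions, batch normalization, pooling, linear layers)
    used by the training and search loops.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
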