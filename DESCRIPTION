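Package: motifforest
Title: Transcription Factor Binding Site Prediction from Sequence and
    DNA Biophysical Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trainable prediction of transcription factor binding sites
    (TFBS) that fuses direct-readout sequence features (one-hot base
    identities and nucleotide position dependencies) with indirect-readout
    biophysical DNA property profiles (bendability, propeller twist,
    stacking energy and related k-mer scales) in a random-forest
    classifier. A short, maximum-recall positional weight matrix
    pre-filter screens candidate windows before classification; decision
    thresholds are calibrated on validation data (maximum precision,
    maximum F-measure and their average) and every hit carries an
    empirical P-value from a background null score distribution. Includes
    a strand-aware FASTA scanner emitting BED6, a packaged registry of
    DNA property scales, and a synthetic-data generator with planted
    motifs and structural signal for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
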