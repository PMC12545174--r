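Package: rnc
Title: Relational Neural Control of In Silico fMRI Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relational neural control (RNC): searching or evolving
    stimulus images that align or disentangle the univariate and multivariate
    fMRI responses of pairs of visual cortical areas, using in silico responses
    produced by encoding models. Implements the random-batch null baselines,
    margin-constrained univariate image selection, elitist genetic search over
    image batches for representational-similarity objectives, GAN-style latent
    evolution with a PNG-complexity penalty, noise-ceiling machinery (NCSNR,
    noise ceiling, noise-ceiling-normalized explained variance), participant-wise
    leave-one-out cross-validation, permutation, prevalence and bootstrap
    inference, and MDS embeddings of area relationships. Ships a synthetic
    visual-cortex simulator and toy image-computable encoders and generator so
    the full pipeline runs without any neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
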