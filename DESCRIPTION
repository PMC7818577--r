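Package: securelr
Title: Secure Two-Party Logistic Regression over Additive Secret Shares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Privacy-preserving training of logistic-regression-like models
    (clipped-ReLU activation) on data secret-shared between two computing
    parties, with a trusted initializer distributing correlated randomness.
    Implements exact fixed-point arithmetic over Z_{2^lambda}, additive secret
    sharing in Z_{2^lambda} and Z_2, Beaver-triple multiplication for scalars,
    inner products and matrices, communication-free truncation, ripple-carry
    and carry-lookahead secure bit decomposition, bit-to-ring share conversion,
    and a comparison-free secure clipped-ReLU protocol, composed into a full
    gradient-descent training protocol. Includes in-the-clear float and
    fixed-point reference trainers, a synthetic gene-expression-like data
    generator, instrumented channel accounting (rounds, messages, bytes), and
    broom-style tidiers for fitted models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    purrr,
    rlang,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
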