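Package: snppca
Title: SNP Codings, PCA Variants, and Biplots for Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for elucidating population structure from biallelic SNP
    matrices. Implements per-SNP polarity recoding (rare allele coded 1,
    common allele coded 1, VCF-style reference coding, and mixed schemes),
    six centering and standardization variants of principal components
    analysis with double-centered PCA (DC-PCA) as the recommended default,
    three-source ANOVA of the SNP-by-Individual two-way layout with Gollob
    degrees of freedom for multiplicative terms, augmented ANOVA tables that
    partition each principal component's sum of squares into main-effect and
    interaction portions, the additive main effects and multiplicative
    interaction (AMMI) model with AMMI1 biplot coordinates, correspondence
    analysis with CA1-ranked matrix arrangement and a diagonal-concentration
    randomization test, coherent group-coloring schemes for biplot panels,
    and synthetic genotype generators for gradient-structured and
    effect-structured matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
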