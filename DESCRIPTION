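Package: avephylo
Title: Whole-Genome Phylogenies from Averaged Best-Hit E-Value Similarities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds distance-based phylogenetic trees from whole-genome
    protein similarity. All-vs-all best-hit E-values between two proteomes
    are summarised on a two-dimensional log-scale plot into a slope m and
    the dissimilarity statistic tan(theta), calibrated against 16S rDNA
    substitution rates through an exponential regression, and converted
    into the F family of genome distances (F_AV, F_XY, F_YX, F_H, F_L).
    Includes neighbor-joining tree construction, majority-rule consensus,
    a bootstrap that resamples best-matched protein pairs, Robinson-Foulds
    topology comparison, gene-content reduction experiments, and synthetic
    data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    minpack.lm,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
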