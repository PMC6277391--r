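Package: limnodigest
Title: Quantitative Analyses of Wood Digestion by the Marine Woodborer Limnoria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantitative stages used
    to characterise lignocellulose digestion in the gribble (Limnoria):
    feeding-experiment mass balance and biomass compositional fractionation
    (acetyl bromide-soluble lignin, TFA and sulfuric-acid sugar fractions with
    HPAEC calibration), emPAI-based label-free digestive-proteome
    quantification with tryptic in silico digestion, CPMG relaxometry with
    regularized non-negative inverse Laplace inversion and log-Gaussian
    pore-population deconvolution, and thermal-shift melting-curve fitting.
    A synthetic-data generator emulates the experimental designs so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
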