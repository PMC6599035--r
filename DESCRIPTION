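Package: pacemakeR
Title: Quantitative Proteomics and Biophysical Modelling of the Cardiac Pacemaker
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for label-free quantitative proteomics of the sinus node and
    its translation into biophysics. Implements Perseus-style differential
    protein-abundance analysis (filtering, quantile normalisation, downshifted
    imputation of left-censored missing values, S0-moderated t-statistics with
    permutation-based FDR), absolute ion-channel copy-number estimation from
    iBAQ intensities anchored on a Markov-chain single-channel model of the
    HCN4 pacemaker channel, stochastic single-channel Monte Carlo simulation
    with unitary-conductance fitting, and a configurable Hodgkin-Huxley
    myocyte model supporting proteomics-driven conversion between atrial and
    sinus-node action-potential phenotypes. A synthetic-data module generates
    proteomics matrices and channel tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
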