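Package: unicort
Title: Transmit Field Bias Correction for Variable Flip-Angle R1 Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and removal of radio-frequency transmit (B1+) induced
    multiplicative bias in variable flip-angle (VFA) R1 relaxometry of the
    brain, without a measured B1+ map. Apparent R1 maps computed from a
    proton-density-weighted and a T1-weighted spoiled gradient-echo (FLASH)
    pair are modelled as true R1 times a smooth multiplicative bias field; the
    bias is estimated by penalized maximum likelihood under a Gaussian-mixture
    tissue model with an exponential cosine-basis (DCT) log-bias field,
    optimized by expectation-maximization with Gauss-Newton bias updates. The
    package also provides the spoiled gradient-echo forward physics (Ernst
    equation and its rational approximation), a digital head phantom with
    parametric transmit-field inhomogeneities for validation with known ground
    truth, reference-standard correction with a measured B1+ map, symmetric
    deviation metrics, and a regularization-by-smoothness grid evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, RNifti, jsonlite, yaml, igraph
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'volume-io.R'
    'basis.R'
    'vfa.R'
    'mixture.R'
    'fit-bias.R'
    'unicort.R'
    'evaluate.R'
    'phantom.R'
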