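Package: vcdml
Title: Machine-Learning-Aided Vibrational Circular Dichroism Spectra of
    Conformer Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting conformer vibrational circular dichroism
    (VCD) spectra from dihedral-angle descriptors of molecular geometry and
    for composing Boltzmann-weighted molecular spectra that mix
    quantum-chemistry reference spectra with surrogate predictions.
    Provides Lorentzian band broadening of line spectra onto a fixed
    wavenumber grid, sin/cos torsion featurization with bisector encoding
    and hydrogen-bond distance features, a feed-forward neural-network
    surrogate with tree-structured Parzen estimator hyperparameter search,
    enantiomer and degenerate-pair data augmentation, cosine-similarity
    evaluation, hybrid DFT/ML ensemble composition with cost accounting,
    and a synthetic chirality-aware conformer generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
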