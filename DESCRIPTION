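Package: corouq
Title: Uncertainty Quantification for Reduced-Order Coronary Stenosis Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward uncertainty quantification and global sensitivity analysis
    for computed fractional flow reserve (FFR) and average proximal wall shear
    stress in an idealized eccentric coronary stenosis. Provides a parametric
    stenosis geometry generator with STL/VTK surface export, a transient
    quasi-one-dimensional hemodynamics solver coupled to a lumped-parameter
    microcirculation outlet (with hyperemia modelled as quartered microvascular
    resistance), seeded Latin hypercube sampling of uniform uncertain inputs,
    point-collocation polynomial chaos surrogates fitted by least squares, and
    main/total Sobol sensitivity indices obtained from the orthonormal
    coefficient partition, together with density estimates, prediction
    intervals, convergence studies over polynomial order and oversampling
    ratio, and analytic benchmark problems with closed-form Sobol indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lhs,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
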