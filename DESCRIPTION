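Package: ntfam
Title: Bivariate Nuclear Twin Family Models with Assortative Mating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural-equation modelling of two correlated traits in
    nuclear twin families (monozygotic and dizygotic twins, their siblings
    and parents). Implements expected family moments under primary phenotypic
    assortative mating (a 2x2 copath matrix and the equilibrium
    additive-genetic covariance matrix q) or social homogamy, qualitative and
    quantitative sex limitation, full-information maximum likelihood over
    families with arbitrary missingness, likelihood-ratio and AIC model
    selection, and the decomposition of a cross-trait genetic correlation
    into pleiotropy versus gametic phase disequilibrium. A generational
    forward simulator with copula-based mate matching generates family data
    with the exact structure the model assumes and doubles as a brute-force
    oracle for the analytic moments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
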