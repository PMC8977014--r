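Package: mpclogit
Title: Privacy-Preserving Logistic Regression over Additively Secret-Shared Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates secure multi-party training of logistic regression models
    over horizontally partitioned data using n-out-of-n additive secret sharing.
    Implements both an honest-majority three-party multiplication protocol with
    re-sharing and a dishonest-majority two-party protocol based on Beaver
    multiplication triples from a trusted initializer, an iterative
    (Newton-Raphson) secure matrix inversion, exact and least-squares-polynomial
    secure sigmoid evaluation, and fixed-Hessian Newton-Raphson coefficient
    estimation. Every protocol message passes through an instrumented queue so
    communication costs (messages and bits) are accounted exactly, and a
    plaintext reference implementation is included for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
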