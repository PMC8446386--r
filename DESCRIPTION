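Package: tcvcd
Title: Theoretical Construct Validity for Cognitive Diagnostic Test Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating cognitive diagnostic test designs before any
    data are collected. Given an attribute hierarchy and a test Q-matrix, the
    package derives the knowledge states reachable from the test via the
    Boolean-union augment algorithm and computes the theoretical construct
    validity (TCV), the upper bound of the pattern match ratio (PMR) of
    examinee classification. It also constructs ideal-response partitions of
    the knowledge-state space (proving the TCV = PMR upper-bound identity
    constructively), simulates noisy responses under the DINA model with
    maximum-likelihood classification, and orchestrates full simulation
    studies comparing empirical PMR against TCV across hierarchy structures,
    examinee distributions and item-category mixes.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
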