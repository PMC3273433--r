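Package: nullox
Title: X-Chromosome Mis-Segregation Analysis for Drosophila SPO11 Bioassays
Version: 1.0.0
Authors@R:
    person("Nullox", "Developers", email = "nullox@example.org",
           role = c("aut", "cre"))
Description: Quantifies meiotic X-chromosome mis-segregation in Drosophila
    genetic crosses used as a bioassay for SPO11 double-strand-break (DSB)
    activity. Implements a forward probabilistic model from oocyte fates
    (meiosis-I nondisjunction versus DSB-induced chromosome loss) to scored
    progeny classes (X0 sons, XXY daughters), the excess nullo-X statistic
    with chi-square tests against a control cross, maximum-likelihood
    recovery of the two mis-segregation rates from progeny counts with
    profile-likelihood and parametric-bootstrap intervals, seeded simulators
    of cross, fecundity and oocyte-cytology count tables, tab-separated
    readers and writers for all of them, and a command-line pipeline that
    assembles reproducible analysis reports.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
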