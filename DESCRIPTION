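Package: rtici
Title: Tumor-Immune Dynamics of Combined Radiotherapy and CTLA-4 Checkpoint
    Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Four-compartment ordinary-differential-equation model of the
    interaction between irradiated tumor cells, dying tumor cells,
    non-irradiated (metastatic) tumor cells and circulating lymphocytes under
    radiotherapy and CTLA-4 immune-checkpoint inhibition (tremelimumab).
    Radiation kill follows the linear-quadratic model and is applied as
    instantaneous impulses at scheduled fraction times; checkpoint-inhibitor
    efficacy decays exponentially with the drug half-life.  Includes a seeded
    virtual-patient cohort generator, RECIST 1.1 response classification of
    simulated lesion diameters, calibration of the efficacy distribution
    against reported trial response rates by grid search over convolved
    response curves, and in-silico experiments on treatment modality,
    irradiated tumor burden and treatment sequencing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
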