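Package: cwqsar
Title: Monte Carlo Correlation-Weight QSAR Models from SMILES Optimal Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds one-variable QSAR regression models of the CORAL family for
    continuous toxicity endpoints such as NOAEL and LOAEL from repeated-dose
    studies. Molecular attributes (SMILES n-grams, Morgan extended connectivity,
    nearest-neighbour codes and atom-pair proportions) are extracted from SMILES
    strings and hydrogen-suppressed molecular graphs; per-attribute correlation
    weights are optimised by a seeded Monte Carlo hill climb against a target
    function combining active- and passive-training correlations with the index
    of ideality of correlation (IIC) and the correlation intensity index (CII)
    evaluated on a calibration set. The summed weights form the descriptor of
    correlation weights (DCW) entering an ordinary least-squares calibration
    Endpoint = C0 + C1 * DCW. Includes dataset curation utilities, a full
    external-validation metric suite (R2, Q2, Q2F3, CCC, IIC, CII, MAE, RMSE, F),
    a probabilistic applicability domain based on the statistical SMILES defect,
    a synthetic-data generator with planted linear truth for end-to-end testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
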