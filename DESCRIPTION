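Package: cirbe
Title: Empirical Carbon-Ion Relative Biological Effectiveness Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts carbon-ion linear-quadratic cell-survival parameters and
    relative biological effectiveness (RBE) from photon reference
    radiosensitivity and dose-weighted LET, using an empirical four-parameter
    model built on the linear correlation between photon and carbon-ion
    radiosensitivity endpoints. Provides the closed-form prediction chain,
    delta-method confidence bands, model training by multi-start nonlinear
    least squares on a normalized survival-curve distance with BIC/AICc model
    selection, leave-one-out cross-validation with bootstrap prediction
    intervals and LET-binned accuracy summaries, a synthetic training-data
    generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
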