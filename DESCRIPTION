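Package: asircast
Title: Attention-LSTM Forecasting of Stratified Incidence Rates with
    Particle Swarm Hyperparameter Tuning
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-step forecasting of age- and sex-stratified annual
    incidence rates (ASIR panels in the Global Burden of Disease long-CSV
    shape). Implements a single-layer LSTM encoder with additive attention
    pooling and a single-shot multi-horizon linear head, trained with Adam,
    L2 regularization and early stopping; hyperparameters (hidden units,
    dropout, learning rate, batch size) are selected by a from-scratch
    particle swarm optimizer under calendar-anchored expanding-window
    time-series cross-validation. Includes a synthetic stratified-incidence
    generator, the five standard forecast-accuracy metrics (MSE, R2, MAPE,
    NRMSE, MAE), ARIMA/SVR/random-forest/plain-LSTM baselines, an ablation
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
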