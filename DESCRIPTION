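Package: troughcast
Title: Vancomycin Trough Forecasting and Dose Recommendation from ICU Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts steady-state vancomycin trough concentrations two days in
    advance for critically ill adults from intensive-care time-series data, and
    recommends dose adjustments that steer the predicted trough into the
    patient-specific therapeutic range. Provides a seeded synthetic ICU cohort
    generator built on one-compartment intermittent-infusion pharmacokinetics,
    patient-day eligibility filtering, hourly feature engineering with
    last-observation-carried-forward imputation, a sequence regressor combining
    an LSTM with multi-head self-attention and a dose skip connection (trained
    by backpropagation implemented in the package), gradient-times-input feature
    attribution, regression and therapeutic-category evaluation statistics
    (MAE/RMSE/MAPE, confusion matrices, Bland-Altman, paired t and McNemar
    comparisons), and a 250 mg line-search dose recommender with a
    proximity-to-range reward.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
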