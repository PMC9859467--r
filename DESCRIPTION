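Package: bracquant
Title: Breath Alcohol Quantification from Fuel-Cell Sensor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal processing and analytical calibration for fuel-cell
    breath-alcohol sensors. Provides a synthetic sensor-trace simulator
    (digitized electrochemical response sampled at 50 ms), extraction of the
    seven signal features used for quantification, a four-rule threshold
    classifier that rejects alcohol-free samples, peak-averaged linear
    calibration of ADC counts against breath alcohol content (BrAC),
    a full analytical validation metric suite (accuracy, MSE, MAE, RMSE,
    R-squared, SD, RSD), BrAC/BAC unit conversion, and a mock IoT gateway
    reproducing the device's identity-lookup and measurement-upload protocol.
License: MIT + file LICENSE
Encoding: UTF-8
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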