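Package: gaittrans
Title: Wrist-to-Lower-Limb Inertial Signal Translation and Gait Event Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Translates six-channel inertial measurements (tri-axial
    acceleration and angular velocity) recorded at the wrist into the
    signals a tibia- or shoe-mounted sensor would record, using four
    neural sequence-to-sequence architectures (a dense autoencoder, a
    1-D convolutional autoencoder, a CNN-LSTM hybrid and a 1-D U-Net)
    trained with a two-stage protocol: unsupervised wrist pretraining,
    encoder freezing, paired translation training and low-rate
    fine-tuning.  Includes per-channel MAE/RMSE evaluation in physical
    units, a Butterworth-filtered gyroscope gait-event detector
    (toe-off and heel-strike) with stride/stance/swing temporal
    parameters, and a synthetic paired-IMU gait simulator that provides
    ground-truth events for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
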